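# Fold-change analysis with a calibrator level (ddCt method) and
# relative-expression analysis (dCt method) from factorial designs.

#' Fold-change analysis by ANOVA / ANCOVA with a calibrator
#'
#' Fits a linear (mixed) model on the weighted delta-Ct scale (see
#' [fit_wdct_model()]), extracts estimated marginal means for the levels of
#' the main factor, and reports each non-calibrator level as a fold change
#' against the calibrator: `FC = 2^-(emmean_level - emmean_calibrator)`,
#' with t-based p-values and back-transformed confidence limits and
#' standard-error bounds. The calibrator's own row reports FC 1 and p 1 by
#' convention (its `se_log2` is the standard error of its marginal mean; its
#' confidence limits are not defined and are reported as `NA`).
#'
#' Under `"anova"` the factors enter as a full factorial; if any interaction
#' involving the main factor is significant at `alpha`, a warning is issued
#' because fold changes between main-factor levels alone may then be
#' misleading. Under `"ancova"` the other factors enter additively as
#' covariates.
#'
#' @inheritParams fit_wdct_model
#' @param calibrator Level of `main_factor` used as the reference condition;
#'   defaults to its first level.
#' @param p_adjust Adjustment across the non-calibrator contrasts
#'   (default `"none"`; significance marks use the adjusted value when a
#'   method is selected).
#' @param level Confidence level.
#' @param alpha Significance threshold for the interaction warning.
#' @return A tibble of class `qpcr_fc` with one row per main-factor level
#'   (calibrator first): `contrast`, `fc`, `p_value`, `p_adj`, `sig`, `lcl`,
#'   `ucl`, `se_log2`, `lower_se`, `upper_se`, `df`. The underlying
#'   `qpcr_fit` is attached as attribute `"fit"`.
#' @examples
#' d <- simulate_qpcr(list(treatment = c("L1", "L2", "L3")), n_rep = 3,
#'                    true_re = c(1, 2, 8), noise_sd = 0.15, seed = 2)
#' suppressWarnings(qpcr_anova_fc(d, calibrator = "L1"))
#' @export
qpcr_anova_fc <- function(data, main_factor = NULL, calibrator = NULL,
                          analysis_type = c("anova", "ancova"),
                          p_adjust = "none", level = 0.95, alpha = 0.05) {
  fit <- if (inherits(data, "qpcr_fit")) data else {
    fit_wdct_model(data, main_factor = main_factor,
                   analysis_type = analysis_type)
  }
  main_factor <- fit$main_factor
  lv <- levels(factor(fit$data[[main_factor]]))
  calibrator <- calibrator %||% lv[1]
  if (!calibrator %in% lv) {
    abort(sprintf("Calibrator '%s' is not a level of %s (levels: %s).",
                  calibrator, main_factor, paste(lv, collapse = ", ")))
  }

  em <- model_emmeans(fit, main_factor, level = level)
  em_sum <- as.data.frame(summary(em, level = level))
  con <- emmeans::contrast(em, "trt.vs.ctrl",
                           ref = which(lv == calibrator))
  cs <- as.data.frame(summary(con, adjust = "none", level = level,
                              infer = c(TRUE, TRUE)))

  cal_row <- em_sum[em_sum[[main_factor]] == calibrator, ]
  out <- dplyr::bind_rows(
    tibble(
      contrast = calibrator, fc = 1, p_value = 1,
      lcl = NA_real_, ucl = NA_real_,
      se_log2 = cal_row$SE, df = cal_row$df
    ),
    tibble(
      contrast = gsub(" - ", " vs ", cs$contrast),
      fc = 2^(-cs$estimate),
      p_value = cs$p.value,
      lcl = 2^(-cs$upper.CL),
      ucl = 2^(-cs$lower.CL),
      se_log2 = cs$SE,
      df = cs$df
    )
  )
  out$p_adj <- c(1, adjust_pvalues(cs$p.value, p_adjust))
  p_for_sig <- if (identical(p_adjust, "none")) out$p_value else out$p_adj
  out <- out |>
    dplyr::bind_cols(se_backtransform(out$fc, out$se_log2)) |>
    dplyr::mutate(sig = dplyr::if_else(.data$contrast == calibrator, "",
                                       sig_marks(p_for_sig))) |>
    dplyr::select("contrast", "fc", "p_value", "p_adj", "sig", "lcl", "ucl",
                  "se_log2", "lower_se", "upper_se", "df")

  warn_significant_interactions(fit, main_factor, alpha)
  structure(out, class = c("qpcr_fc", class(tibble())),
            fit = fit, calibrator = calibrator, main_factor = main_factor,
            p_adjust = p_adjust, level = level)
}

warn_significant_interactions <- function(fit, main_factor, alpha) {
  tab <- tidy(fit)
  inter <- tab[grepl(":", tab$term) &
                 vapply(strsplit(tab$term, ":"),
                        function(tt) main_factor %in% tt, logical(1)), ]
  sig <- inter$term[!is.na(inter$p.value) & inter$p.value < alpha]
  if (length(sig)) {
    warn(paste0(
      "Interaction(s) involving ", main_factor, " significant at ", alpha,
      " (", paste(sig, collapse = ", "),
      "); fold changes between ", main_factor,
      " levels alone may be misleading. Consider qpcr_means() with slicing."
    ))
  }
  invisible(sig)
}

#' Relative-expression analysis by ANOVA
#'
#' The delta-Ct method for 1-3 factor designs: fits the full-factorial
#' (mixed) model on the weighted delta-Ct scale and reports, for every
#' factor-level combination, the relative expression `RE = 2^-emmean`,
#' back-transformed confidence limits and standard-error bounds, the
#' standard deviation of the back-transformed per-replicate values, and a
#' compact letter display summarizing all pairwise comparisons (combinations
#' sharing no letter differ significantly at `alpha`). Rows are sorted by RE
#' descending.
#'
#' @inheritParams qpcr_anova_fc
#' @param p_adjust Adjustment applied to the pairwise p-values before
#'   letter grouping (default `"none"`).
#' @param alpha Significance level for the letter display.
#' @return A tibble of class `qpcr_re`, one row per factor-level
#'   combination: the factor columns, `re`, `lcl`, `ucl`, `se_log2`,
#'   `lower_se`, `upper_se`, `sd`, `letters`. The `qpcr_fit` is attached as
#'   attribute `"fit"`, the pairwise comparisons as `"pairwise"`.
#' @examples
#' d <- simulate_qpcr(list(geno = c("S", "R"), dose = c("0", "0.5")),
#'                    n_rep = 3, true_re = c(1, 1, 1, 3), noise_sd = 0.15,
#'                    seed = 3)
#' suppressWarnings(qpcr_anova_re(d))
#' @export
qpcr_anova_re <- function(data, p_adjust = "none", level = 0.95,
                          alpha = 0.05) {
  fit <- if (inherits(data, "qpcr_fit")) data else fit_wdct_model(data)
  factors <- fit$factors
  counts <- dplyr::count(as_tibble(fit$data), dplyr::across(dplyr::all_of(factors)))
  full <- rev(expand.grid(rev(lapply(fit$data[factors],
                                     function(f) levels(factor(f))))))
  names(full) <- factors
  present <- do.call(paste, c(counts[factors], sep = ":"))
  wanted <- do.call(paste, c(full, sep = ":"))
  if (length(miss <- setdiff(wanted, present))) {
    abort(paste0("Factor-level combination(s) with no observations: ",
                 paste(miss, collapse = ", ")))
  }

  em <- model_emmeans(fit, factors, level = level)
  es <- as.data.frame(summary(em, level = level))
  label <- do.call(paste, c(es[factors], sep = ":"))

  # pairwise comparisons and their symmetric p matrix for the letter display
  prs <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                               adjust = p_adjust, infer = c(FALSE, TRUE)))
  pmat <- pairwise_p_matrix(label, prs, es, factors)

  # replicate-scale SD of the back-transformed values within each cell
  sd_tbl <- fit$data |>
    as_tibble() |>
    dplyr::mutate(.label = do.call(paste, c(lapply(dplyr::pick(dplyr::all_of(factors)), as.character),
                                            sep = ":"))) |>
    dplyr::summarise(sd = sd(2^(-.data$wdct)), .by = ".label")

  out <- dplyr::bind_cols(
    as_tibble(es[factors]),
    tibble(
      .label = label,
      re = 2^(-es$emmean),
      lcl = 2^(-es$upper.CL),
      ucl = 2^(-es$lower.CL),
      se_log2 = es$SE,
      df = es$df
    )
  ) |>
    dplyr::left_join(sd_tbl, by = ".label") |>
    dplyr::arrange(dplyr::desc(.data$re))
  out <- dplyr::bind_cols(out, se_backtransform(out$re, out$se_log2))
  out$letters <- compact_letter_display(pmat[out$.label, out$.label],
                                        alpha = alpha)
  out <- dplyr::select(out, dplyr::all_of(factors), "re", "lcl", "ucl",
                       "se_log2", "lower_se", "upper_se", "sd", "letters")

  structure(out, class = c("qpcr_re", class(tibble())),
            fit = fit, factor_cols = factors, alpha = alpha,
            p_adjust = p_adjust, level = level,
            pairwise = as_tibble(prs))
}

# build a symmetric p-value matrix from emmeans pairwise contrast output
pairwise_p_matrix <- function(labels, prs, es, factors) {
  # emmeans labels combinations of multiple factors with spaces or commas in
  # "contrast"; reconstruct from the emmean grid ordering instead
  n <- length(labels)
  pmat <- matrix(1, n, n, dimnames = list(labels, labels))
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      pmat[i, j] <- pmat[j, i] <- prs$p.value[k]
    }
  }
  if (k != nrow(prs)) {
    abort("Internal error: pairwise contrast count does not match the mean grid.")
  }
  pmat
}
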