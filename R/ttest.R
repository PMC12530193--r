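# Two-condition fold-change analysis. Inference happens on the weighted
# delta-Ct scale (normal there); results are back-transformed with
# y = 2^-x in the final step.

#' Fold-change analysis of a two-condition experiment by t-test
#'
#' For each target gene, pairs every observation with the same-replicate
#' reference-gene observation(s) to form weighted delta-Ct values (see
#' [wdct()]), then compares treatment vs control wdct with a two-sample or
#' paired t-test. The fold change is `2^-(mean_Tr - mean_Co)`; its standard
#' error is the standard error of the mean difference on the log2 scale, and
#' the confidence limits are the back-transformed t-interval.
#'
#' Replicate pairing is positional: within each condition, the i-th row of
#' every gene belongs to the i-th biological replicate. The layout carries no
#' replicate column, so rows must be ordered consistently across genes;
#' tables from [simulate_ttest()] and the standard layout convention satisfy
#' this by construction.
#'
#' @param data A ttest-layout `qpcr_tbl` (see [qpcr_table()]): columns
#'   condition (control level first), gene (reference gene(s) last),
#'   efficiency, Ct.
#' @param paired Use a paired t-test (replicates must correspond across
#'   conditions).
#' @param var_equal Assume equal variances (pooled test); `FALSE` gives the
#'   Welch test.
#' @param p_adjust Method for adjusting p-values across genes, default
#'   `"BH"`; `"none"` disables adjustment.
#' @param level Confidence level for the fold-change limits.
#' @return A tibble of class `qpcr_fc`, one row per target gene: `gene`,
#'   `fc`, `lcl`, `ucl`, `p_value`, `p_adj`, `sig` (from the adjusted p when
#'   adjustment is on: `**` <= 0.01, `*` <= 0.05, `.` <= 0.1), `se_log2`,
#'   `lower_se`, `upper_se`, `df`, `statistic`.
#' @examples
#' d <- simulate_ttest(n_rep = 6, true_fc = c(geneA = 4), noise_sd = 0.2,
#'                     seed = 7)
#' qpcr_ttest(d)
#' @export
qpcr_ttest <- function(data, paired = FALSE, var_equal = TRUE,
                       p_adjust = "BH", level = 0.95) {
  if (!inherits(data, "qpcr_tbl") || qpcr_meta(data)$layout != "ttest") {
    data <- qpcr_table(data, "ttest")
  }
  m <- qpcr_meta(data)
  wd <- ttest_wdct(data, m)

  results <- purrr::map_dfr(m$target_genes, function(g) {
    gw <- dplyr::filter(wd, .data$gene == g)
    tr <- gw$wdct[gw$condition != m$control]
    co <- gw$wdct[gw$condition == m$control]
    if (paired && length(tr) != length(co)) {
      abort(sprintf("Gene %s: paired test needs equal replicate counts (found %d vs %d).",
                    g, length(tr), length(co)))
    }
    if (paired && length(tr) == length(co) && sd(tr - co) == 0) {
      abort(sprintf("Gene %s: zero variance of the paired wdct differences; the t-test is undefined.", g))
    }
    if (!paired && sd(tr) == 0 && sd(co) == 0) {
      abort(sprintf("Gene %s: zero wdct variance in both conditions; the t-test is undefined.", g))
    }
    tt <- t.test(tr, co, paired = paired, var.equal = var_equal,
                 conf.level = level)
    diff <- mean(tr) - mean(co)
    fc <- fold_change(mean(tr), mean(co))
    se <- unname(tt$stderr)
    # CI on the difference maps to a reversed FC interval under 2^-x
    tibble(
      gene = g, fc = fc,
      lcl = 2^(-tt$conf.int[2]), ucl = 2^(-tt$conf.int[1]),
      p_value = unname(tt$p.value), se_log2 = se,
      df = unname(tt$parameter), statistic = unname(tt$statistic)
    )
  })

  results$p_adj <- adjust_pvalues(results$p_value, p_adjust)
  p_for_sig <- if (identical(p_adjust, "none")) results$p_value else results$p_adj
  results <- results |>
    dplyr::bind_cols(se_backtransform(results$fc, results$se_log2)) |>
    dplyr::mutate(sig = sig_marks(p_for_sig)) |>
    dplyr::select("gene", "fc", "lcl", "ucl", "p_value", "p_adj", "sig",
                  "se_log2", "lower_se", "upper_se", "df", "statistic")
  structure(results,
            class = c("qpcr_fc", class(tibble())),
            p_adjust = p_adjust, level = level,
            paired = paired, var_equal = var_equal)
}

# per-gene wdct with positional replicate pairing against the reference
# gene(s)
ttest_wdct <- function(data, m) {
  indexed <- data |>
    as_tibble() |>
    dplyr::mutate(.rep = dplyr::row_number(),
                  .by = c("condition", "gene"))
  refs <- indexed |>
    dplyr::filter(.data$gene %in% m$ref_genes) |>
    dplyr::mutate(ref_idx = match(.data$gene, m$ref_genes)) |>
    dplyr::select("condition", ".rep", "ref_idx", ref_e = "e", ref_ct = "ct") |>
    tidyr::pivot_wider(names_from = "ref_idx",
                       values_from = c("ref_e", "ref_ct"))
  indexed |>
    dplyr::filter(.data$gene %in% m$target_genes) |>
    dplyr::left_join(refs, by = c("condition", ".rep")) |>
    dplyr::mutate(wdct = if (m$n_ref == 2) {
      wdct(.data$e, .data$ct, .data$ref_e_1, .data$ref_ct_1,
           .data$ref_e_2, .data$ref_ct_2)
    } else {
      wdct(.data$e, .data$ct, .data$ref_e_1, .data$ref_ct_1)
    })
}

#' Welch (unequal-variance) t-test
#'
#' Two-sample t-test under the unequal-variances hypothesis, with the
#' Welch-Satterthwaite degrees of freedom. Exposed for direct use on wdct
#' values; [qpcr_ttest()] uses the same test when `var_equal = FALSE`.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `estimate`
#'   (mean difference a - b) and `se`.
#' @examples
#' welch_ttest(c(3.0, 3.2, 2.8), c(5.0, 5.2, 4.8))
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = unname(tt$p.value),
         estimate = unname(diff(rev(tt$estimate))),
         se = unname(tt$stderr))
}
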