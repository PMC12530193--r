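# Marginal-means comparisons for any effect of a fitted wdct model,
# including simple effects and slices, back-transformed to the fold-change
# scale.

#' Pairwise marginal-means comparisons on the fold-change scale
#'
#' Computes estimated marginal means on the weighted delta-Ct scale for any
#' effect present in a fitted model (optionally sliced by another factor's
#' levels via `by`), forms all pairwise contrasts, and back-transforms each
#' contrast to a fold change with Eq.-6-style standard-error bounds and
#' t-based confidence limits. Marginal means weight the design cells
#' equally.
#'
#' @param fit A `qpcr_fit` from [fit_wdct_model()], or a `qpcr_fc` /
#'   `qpcr_re` result carrying one as its `"fit"` attribute.
#' @param specs Character vector of factor name(s) defining the effect,
#'   e.g. `"treatment"` or `c("treatment", "dose")`.
#' @param by Optional factor name: compare `specs` separately within each
#'   level of `by` (slicing).
#' @param p_adjust Adjustment across the pairwise contrasts (default
#'   `"BH"`).
#' @param level Confidence level.
#' @return A tibble of class `qpcr_fc`: `contrast` (plus a `by` column when
#'   slicing), `fc`, `p_value`, `p_adj`, `sig`, `lcl`, `ucl`, `se_log2`,
#'   `lower_se`, `upper_se`, `df`. The marginal means on the wdct scale are
#'   attached as attribute `"emmeans"`.
#' @examples
#' d <- simulate_qpcr(list(treatment = c("L1", "L2", "L3")), n_rep = 3,
#'                    true_re = c(1, 2, 8), noise_sd = 0.15, seed = 2)
#' fit <- fit_wdct_model(d)
#' qpcr_means(fit, "treatment")
#' @export
qpcr_means <- function(fit, specs, by = NULL, p_adjust = "BH",
                       level = 0.95) {
  if (!inherits(fit, "qpcr_fit")) {
    fit <- attr(fit, "fit")
    if (!inherits(fit, "qpcr_fit")) {
      abort("`fit` must be a qpcr_fit or a result object carrying one.")
    }
  }
  known <- fit$factors
  bad <- setdiff(c(specs, by), known)
  if (length(bad)) {
    abort(sprintf("Effect(s) not in the model: %s. Available factors: %s.",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  if (fit$analysis_type == "ancova" &&
      (length(specs) > 1 || !is.null(by))) {
    abort("ANCOVA models are additive; only simple effects can be compared. Refit with analysis_type = 'anova' for interactions or slicing.")
  }
  em <- model_emmeans(fit, specs, by = by, level = level)
  prs <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                               adjust = "none", infer = c(TRUE, TRUE)))
  out <- tibble(
    contrast = gsub(" - ", " vs ", prs$contrast),
    fc = 2^(-prs$estimate),
    p_value = prs$p.value,
    p_adj = adjust_pvalues(prs$p.value, p_adjust),
    lcl = 2^(-prs$upper.CL),
    ucl = 2^(-prs$lower.CL),
    se_log2 = prs$SE,
    df = prs$df
  )
  if (!is.null(by)) out <- dplyr::bind_cols(tibble(!!by := prs[[by]]), out)
  p_for_sig <- if (identical(p_adjust, "none")) out$p_value else out$p_adj
  out <- out |>
    dplyr::bind_cols(se_backtransform(out$fc, out$se_log2)) |>
    dplyr::mutate(sig = sig_marks(p_for_sig)) |>
    dplyr::relocate("sig", .after = "p_adj")
  structure(out, class = c("qpcr_fc", class(tibble())),
            fit = fit, p_adjust = p_adjust, level = level,
            emmeans = as_tibble(as.data.frame(summary(em, level = level))))
}
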