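# Residual diagnostics for wdct models: the t-test/ANOVA machinery assumes
# normal, homoscedastic wdct residuals; when that fails, non-parametric
# alternatives (Mann-Whitney, Kruskal-Wallis) should be considered instead.

#' Residual diagnostics for a fitted wdct model
#'
#' Runs a Shapiro-Wilk test for normality of the residuals and a
#' Brown-Forsythe/Levene-type test (via [car::leveneTest()], median-centred)
#' for homogeneity of variances across the design cells, and returns the
#' data for QQ and residual-vs-fitted plots. When either assumption fails at
#' `alpha`, the advisory names the standard non-parametric alternatives
#' (Mann-Whitney for two groups, Kruskal-Wallis for several); these are
#' advisory only and are not executed.
#'
#' @param fit A `qpcr_fit` from [fit_wdct_model()] (or a result object
#'   carrying one as attribute `"fit"`).
#' @param alpha Threshold used for the advisory text.
#' @return An object of class `qpcr_diagnostics`: a list with `shapiro`
#'   (statistic, p), `levene` (statistic, df, p, or `NULL` when cells have
#'   no replication), `qq` and `residuals_fitted` tibbles, `degenerate`
#'   (TRUE when the residuals are constant), and `advice`.
#' @examples
#' d <- simulate_qpcr(list(treatment = c("L1", "L2")), n_rep = 4,
#'                    true_re = c(1, 4), noise_sd = 0.2, seed = 5)
#' fit <- suppressWarnings(fit_wdct_model(d))
#' residual_diagnostics(fit)
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "qpcr_fit")) fit <- attr(fit, "fit")
  if (!inherits(fit, "qpcr_fit")) abort("`fit` must be a qpcr_fit.")
  res <- unname(residuals(fit$model))
  if (length(res) < 3) abort("Normality diagnostics need at least 3 residuals.")

  degenerate <- isTRUE(sd(res) < 1e-10)
  shap <- if (degenerate) NULL else {
    s <- shapiro.test(res)
    tibble(statistic = unname(s$statistic), p_value = s$p.value)
  }

  cells <- interaction(as_tibble(fit$data)[fit$factors], drop = TRUE)
  lev <- NULL
  if (!degenerate && nlevels(cells) >= 2 && all(table(cells) >= 2)) {
    lt <- car::leveneTest(res, cells, center = median)
    lev <- tibble(statistic = lt[1, "F value"], df1 = lt[1, "Df"],
                  df2 = lt[2, "Df"], p_value = lt[1, "Pr(>F)"])
  }

  qq <- stats::qqnorm(res, plot.it = FALSE)
  advice <- diagnostics_advice(shap, lev, degenerate, alpha, nlevels(cells))
  structure(
    list(
      shapiro = shap, levene = lev,
      qq = tibble(theoretical = qq$x, sample = qq$y),
      residuals_fitted = tibble(fitted = unname(fitted(fit$model)),
                                residual = res),
      degenerate = degenerate, alpha = alpha, advice = advice
    ),
    class = "qpcr_diagnostics"
  )
}

diagnostics_advice <- function(shap, lev, degenerate, alpha, n_groups) {
  if (degenerate) {
    return("Residuals are constant (degenerate fit); diagnostics are uninformative.")
  }
  issues <- c(
    if (!is.null(shap) && shap$p_value < alpha) "residuals depart from normality (Shapiro-Wilk)",
    if (!is.null(lev) && lev$p_value < alpha) "residual variances differ across cells (Levene)"
  )
  if (!length(issues)) {
    return("No evidence against normality or variance homogeneity of the wdct residuals.")
  }
  alt <- if (n_groups <= 2) "the Mann-Whitney (Wilcoxon rank-sum) test" else "the Kruskal-Wallis test (or Mann-Whitney for two groups)"
  paste0("Assumption check failed: ", paste(issues, collapse = "; "),
         ". Parametric results may be unreliable; consider ", alt,
         " on the wdct values, or the unequal-variance t-test where applicable.")
}

#' @export
print.qpcr_diagnostics <- function(x, ...) {
  cat("<qpcr_diagnostics>\n")
  if (!is.null(x$shapiro)) {
    cat(sprintf("  Shapiro-Wilk: W = %.4f, p = %.4g\n",
                x$shapiro$statistic, x$shapiro$p_value))
  }
  if (!is.null(x$levene)) {
    cat(sprintf("  Levene (median-centred): F(%d, %d) = %.4f, p = %.4g\n",
                x$levene$df1, x$levene$df2, x$levene$statistic,
                x$levene$p_value))
  }
  cat(" ", x$advice, "\n")
  invisible(x)
}
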