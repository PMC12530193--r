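# Repeated-measures fold-change analysis: same contrast machinery as the
# factorial analysis, but each physical individual (id) is measured at every
# time point and enters the model as a random intercept.

#' Fold-change analysis of a repeated-measures experiment
#'
#' Fits a mixed model on the weighted delta-Ct scale with fixed effects of
#' time (and treatment, and their interaction, when a treatment column is
#' present) and a random intercept per individual, then reports fold changes
#' of every level of `main_factor` against `baseline`, exactly as
#' [qpcr_anova_fc()] does for independent designs. The random intercept
#' absorbs stable individual-specific expression offsets.
#'
#' @param data A repeated-layout `qpcr_tbl` (see [qpcr_table()]): columns
#'   `id [- treatment] - time - targetE - targetCt - ref1E - ref1Ct
#'   [- ref2E - ref2Ct]`.
#' @param baseline Level of `main_factor` used as calibrator; defaults to
#'   the first time (or treatment) level.
#' @param main_factor `"time"` (default) or `"treatment"`.
#' @inheritParams qpcr_anova_fc
#' @return A `qpcr_fc` tibble as in [qpcr_anova_fc()], baseline row first.
#' @examples
#' d <- simulate_repeated(n_id = 6, true_fc = c(time2 = 4), noise_sd = 0.2,
#'                        id_sd = 0.5, seed = 4)
#' suppressWarnings(qpcr_repeated(d))
#' @export
qpcr_repeated <- function(data, baseline = NULL, main_factor = "time",
                          p_adjust = "none", level = 0.95, alpha = 0.05) {
  if (!inherits(data, "qpcr_tbl") || qpcr_meta(data)$layout != "repeated") {
    data <- qpcr_table(data, "repeated")
  }
  fit <- fit_wdct_model(data, main_factor = main_factor,
                        analysis_type = "anova")
  qpcr_anova_fc(fit, calibrator = baseline, p_adjust = p_adjust,
                level = level, alpha = alpha)
}

#' Simulate a repeated-measures qPCR experiment
#'
#' Each of `n_id` individuals is measured at every time point; an
#' individual-specific normal offset (`id_sd`, log2 units) is shared across
#' that individual's time points, which is the random-intercept structure
#' [qpcr_repeated()] assumes. Fold changes in `true_fc` are relative to the
#' first time point.
#'
#' @param n_id Number of individuals (>= 2).
#' @param true_fc Named vector of true fold changes for the non-baseline
#'   time points (names become time levels; the baseline level is
#'   `"time1"`).
#' @param noise_sd Residual wdct SD (log2 units).
#' @param id_sd SD of the per-individual random intercept (log2 units).
#' @param e,baseline_ref_ct As in [simulate_qpcr()].
#' @param seed Optional integer seed.
#' @return A validated `qpcr_tbl` in the repeated layout.
#' @export
simulate_repeated <- function(n_id, true_fc = c(time2 = 2), noise_sd = 0.25,
                              id_sd = 0, e = 2, baseline_ref_ct = 25,
                              seed = NULL) {
  if (n_id < 2) abort("`n_id` must be >= 2.")
  if (any(true_fc <= 0)) abort("`true_fc` must be positive.")
  times <- c("time1", names(true_fc) %||% paste0("time", 1 + seq_along(true_fc)))
  fc <- c(1, unname(true_fc))
  grid <- tidyr::expand_grid(id = seq_len(n_id), time = times)
  with_seed_maybe(seed, {
    id_eff <- rnorm(n_id, 0, id_sd)
    wdct_val <- -log2(fc[match(grid$time, times)]) + id_eff[grid$id] +
      rnorm(nrow(grid), 0, noise_sd)
    target_ct <- (wdct_val + log2(e) * baseline_ref_ct) / log2(e)
    qpcr_table(tibble(id = grid$id, time = grid$time,
                      target_e = e, target_ct = target_ct,
                      ref1_e = e, ref1_ct = baseline_ref_ct),
               "repeated", n_ref = 1, treatment = FALSE)
  })
}
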