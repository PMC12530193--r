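# Linear (mixed) models on the weighted delta-Ct scale. The biological
# replicate (and block, when present) enter as random intercepts via
# lmerTest; when the random-effect variance is degenerate the model falls
# back to a fixed-effects-only lm fit with a warning.

#' Add the weighted delta-Ct column to a qPCR table
#'
#' Computes [wdct()] per observation from the target and reference E/Ct
#' columns of a factorial or repeated-measures `qpcr_tbl` (averaging the two
#' weighted reference terms when two reference genes are present).
#'
#' @param data A `qpcr_tbl` in the anova/ancova or repeated layout.
#' @return `data` with an added numeric `wdct` column (log2 units).
#' @export
add_wdct <- function(data) {
  if (!inherits(data, "qpcr_tbl")) {
    abort("`data` must be a qpcr_tbl (see qpcr_table()).")
  }
  m <- qpcr_meta(data)
  if (!m$layout %in% c("anova", "ancova", "repeated")) {
    abort(sprintf("Layout '%s' has no target/reference columns; wdct is computed per gene by the layout-specific analysis.", m$layout))
  }
  val <- if (identical(m$n_ref, 2L)) {
    wdct(data$target_e, data$target_ct, data$ref1_e, data$ref1_ct,
         data$ref2_e, data$ref2_ct)
  } else {
    wdct(data$target_e, data$target_ct, data$ref1_e, data$ref1_ct)
  }
  out <- dplyr::mutate(as_tibble(data), wdct = val)
  new_qpcr_tbl(out, m$layout, attr(data, "qpcr_meta"))
}

#' Fit a linear (mixed) model on the weighted delta-Ct scale
#'
#' The response is the per-observation [wdct()]. Under `analysis_type =
#' "anova"` all factors enter as a full factorial (all interactions); under
#' `"ancova"` the model is additive: the main factor plus the other factors
#' as covariates, no interactions. The biological replicate, and the block
#' when present, enter as random intercepts (fitted with
#' [lmerTest::lmer()], Satterthwaite degrees of freedom downstream). If the
#' mixed fit is singular or fails, the model is refitted as a
#' fixed-effects-only [lm()] with a warning.
#'
#' @param data A factorial-layout `qpcr_tbl` (or repeated layout, where the
#'   individual id is the random intercept).
#' @param main_factor The factor of interest; required for `"ancova"` and
#'   for downstream fold-change contrasts. Defaults to the first factor.
#' @param analysis_type `"anova"` (full factorial) or `"ancova"` (additive).
#' @return An object of class `qpcr_fit`: a list with the fitted `model`,
#'   the wdct-augmented `data`, the factor names, and fit metadata. Methods:
#'   `print()`, `anova()`, [tidy()], [glance()], [residual_diagnostics()].
#' @examples
#' d <- simulate_qpcr(list(treatment = c("L1", "L2", "L3")), n_rep = 3,
#'                    true_re = c(1, 2, 8), noise_sd = 0.15, seed = 2)
#' fit <- fit_wdct_model(d)
#' anova(fit)
#' @export
fit_wdct_model <- function(data, main_factor = NULL,
                           analysis_type = c("anova", "ancova")) {
  analysis_type <- match.arg(analysis_type)
  if (!inherits(data, "qpcr_tbl")) abort("`data` must be a qpcr_tbl.")
  m <- qpcr_meta(data)
  data <- add_wdct(data)
  factors <- m$factor_cols
  main_factor <- main_factor %||% factors[length(factors)]
  if (!main_factor %in% factors) {
    abort(sprintf("`main_factor` must be one of: %s.",
                  paste(factors, collapse = ", ")))
  }
  if (nlevels(factor(data[[main_factor]])) < 2) {
    abort(sprintf("`%s` has fewer than 2 levels.", main_factor))
  }

  fixed <- if (analysis_type == "anova" || length(factors) == 1) {
    paste(factors, collapse = " * ")
  } else {
    # covariates first, then the factor of interest (additive only)
    paste(c(setdiff(factors, main_factor), main_factor), collapse = " + ")
  }
  random <- c(
    if (m$layout == "repeated") "id" else "rep",
    if (isTRUE(m$block)) "block"
  )
  random <- intersect(random, names(data))
  fit <- fit_mixed_or_fixed(data, fixed, random)

  structure(
    list(model = fit$model, data = data, factors = factors,
         main_factor = main_factor, analysis_type = analysis_type,
         fixed = fixed, random = fit$random, is_mixed = fit$is_mixed),
    class = "qpcr_fit"
  )
}

fit_mixed_or_fixed <- function(data, fixed, random) {
  if (length(random)) {
    fml <- as.formula(paste("wdct ~", fixed, "+",
                            paste(sprintf("(1 | %s)", random), collapse = " + ")))
    mixed <- tryCatch(
      suppressMessages(lmerTest::lmer(fml, data = data)),
      error = function(e) e
    )
    if (!inherits(mixed, "error")) {
      if (!lme4::isSingular(mixed, tol = 1e-5)) {
        return(list(model = mixed, random = random, is_mixed = TRUE))
      }
      warn(paste0("Random-effect variance for (", paste(random, collapse = ", "),
                  ") is degenerate (singular fit); refitting with fixed effects only."))
    } else {
      warn(paste0("Mixed-model fit failed (", conditionMessage(mixed),
                  "); refitting with fixed effects only."))
    }
  }
  model <- lm(as.formula(paste("wdct ~", fixed)), data = data)
  list(model = model, random = character(), is_mixed = FALSE)
}

#' @export
print.qpcr_fit <- function(x, ...) {
  cat("<qpcr_fit> wdct ~", x$fixed)
  if (x$is_mixed) cat(" + (1 |", paste(x$random, collapse = ") + (1 | "), ")")
  cat("\n  analysis:", x$analysis_type,
      "| engine:", if (x$is_mixed) "lmer (Satterthwaite df)" else "lm",
      "| n =", nrow(x$data), "\n")
  print(anova(x))
  invisible(x)
}

#' @export
anova.qpcr_fit <- function(object, ...) {
  if (object$is_mixed) {
    as.data.frame(anova(object$model))
  } else {
    as.data.frame(anova(object$model))
  }
}

#' Tidy a fitted wdct model
#'
#' @param x A `qpcr_fit`.
#' @param effects `"anova"` (default) returns the ANOVA table as tidy rows;
#'   `"fixed"` returns the fixed-effect coefficients.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @export
tidy.qpcr_fit <- function(x, effects = c("anova", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "anova") {
    tab <- anova(x)
    tibble(
      term = rownames(tab),
      df = tab[["Df"]] %||% tab[["NumDF"]],
      statistic = tab[["F value"]],
      p.value = tab[["Pr(>F)"]]
    )
  } else {
    cf <- if (x$is_mixed) summary(x$model)$coefficients else summary(x$model)$coefficients
    tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, "t value"],
      p.value = cf[, ncol(cf)]
    )
  }
}

#' One-row model summary of a fitted wdct model
#'
#' @param x A `qpcr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: nobs, sigma, logLik, AIC, BIC, df.residual,
#'   engine and analysis type.
#' @export
glance.qpcr_fit <- function(x, ...) {
  mod <- x$model
  tibble(
    nobs = nobs(mod),
    sigma = if (x$is_mixed) stats::sigma(mod) else summary(mod)$sigma,
    logLik = as.numeric(logLik(mod)),
    AIC = AIC(mod),
    BIC = BIC(mod),
    df.residual = df.residual(mod),
    engine = if (x$is_mixed) "lmer" else "lm",
    analysis = x$analysis_type
  )
}

# emmeans for either engine; Satterthwaite df for mixed fits
model_emmeans <- function(fit, specs, by = NULL, level = 0.95) {
  args <- list(fit$model, specs = specs, level = level)
  if (!is.null(by)) args$by <- by
  if (fit$is_mixed) args$lmer.df <- "satterthwaite"
  do.call(emmeans::emmeans, args)
}
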