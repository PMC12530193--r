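# Core quantification arithmetic: efficiency-weighted delta-Ct and the
# back-transformations used to report fold change (FC) and relative
# expression (RE) on the linear scale.

#' Efficiency-weighted delta-Ct
#'
#' Computes the efficiency-weighted delta-Ct,
#' \deqn{w\Delta C_T = \log_2(E_{target}) \cdot CT_{target} -
#'       \log_2(E_{ref}) \cdot CT_{ref},}
#' the log2-scale quantity on which all statistical inference in this package
#' is performed. When the amplification efficiency `E` is exactly 2 for both
#' genes this reduces to the classical \eqn{\Delta C_T}; with gene-specific
#' efficiencies, fold changes computed from these values reproduce the Pfaffl
#' efficiency-corrected ratio.
#'
#' With two reference genes the two weighted reference terms are averaged on
#' the log2 scale, which is equivalent to normalizing against the geometric
#' mean of the two reference-gene quantities.
#'
#' @param target_e,target_ct Amplification efficiency (amplification-factor
#'   scale, e.g. 2 for perfect doubling) and threshold cycle of the target
#'   gene. Vectors are recycled by the usual rules.
#' @param ref_e,ref_ct Efficiency and threshold cycle of the (first)
#'   reference gene.
#' @param ref2_e,ref2_ct Optional second reference gene.
#' @return A numeric vector of weighted delta-Ct values (log2 units).
#' @examples
#' wdct(2, 25, 2, 20)        # classical delta-Ct: 5
#' wdct(1.9, 25, 2, 20)      # efficiency-weighted: 3.15
#' wdct(2, 25, 2, 20, 2, 22) # two reference genes: 4
#' @export
wdct <- function(target_e, target_ct, ref_e, ref_ct,
                 ref2_e = NULL, ref2_ct = NULL) {
  check_efficiency(target_e, "target_e")
  check_efficiency(ref_e, "ref_e")
  if (!all(is.finite(target_ct)) || !all(is.finite(ref_ct))) {
    abort("CT values must be finite.")
  }
  ref_term <- log2(ref_e) * ref_ct
  if (!is.null(ref2_e) || !is.null(ref2_ct)) {
    if (is.null(ref2_e) || is.null(ref2_ct)) {
      abort("Supply both `ref2_e` and `ref2_ct`, or neither.")
    }
    check_efficiency(ref2_e, "ref2_e")
    if (!all(is.finite(ref2_ct))) abort("CT values must be finite.")
    ref_term <- (ref_term + log2(ref2_e) * ref2_ct) / 2
  }
  log2(target_e) * target_ct - ref_term
}

check_efficiency <- function(e, name) {
  if (!all(is.finite(e))) abort(sprintf("`%s` must be finite.", name))
  if (any(e <= 1)) {
    abort(sprintf(
      "`%s` must be > 1 on the amplification-factor scale (log2(E) <= 0 invalidates the weighting).",
      name
    ))
  }
  invisible(e)
}

#' Relative expression from a mean weighted delta-Ct
#'
#' \deqn{RE = 2^{-\overline{w\Delta C_T}}}: expression of the target gene
#' relative to the reference gene(s) within one condition (the delta-Ct
#' method).
#'
#' @param mean_wdct Arithmetic mean of weighted delta-Ct values over
#'   biological replicates (log2 units).
#' @return Relative expression (dimensionless ratio).
#' @examples
#' relative_expression(0)  # 1
#' relative_expression(-2) # 4
#' @export
relative_expression <- function(mean_wdct) {
  if (!all(is.finite(mean_wdct))) abort("`mean_wdct` must be finite.")
  2^(-mean_wdct)
}

#' Fold change between two conditions
#'
#' \deqn{FC = 2^{-(\overline{w\Delta C_T}_{Tr} - \overline{w\Delta C_T}_{Co})}}:
#' average expression in the treatment (or non-calibrator) condition relative
#' to the control/calibrator condition (the delta-delta-Ct method). Equal to
#' `relative_expression(mean_wdct_tr) / relative_expression(mean_wdct_co)`.
#'
#' @param mean_wdct_tr,mean_wdct_co Mean weighted delta-Ct in the treatment
#'   and control condition (log2 units).
#' @return Fold change (dimensionless ratio).
#' @examples
#' fold_change(3, 5) # 4
#' @export
fold_change <- function(mean_wdct_tr, mean_wdct_co) {
  if (!all(is.finite(mean_wdct_tr)) || !all(is.finite(mean_wdct_co))) {
    abort("mean wdct values must be finite.")
  }
  2^(-(mean_wdct_tr - mean_wdct_co))
}

#' Livak (2^-ddCt) fold change
#'
#' The classical Livak fold change computed directly from plain delta-Ct
#' values. When every amplification efficiency equals 2, [fold_change()] on
#' [wdct()] values is algebraically identical to this formula; the function
#' is exposed so that reduction can be checked explicitly.
#'
#' @param dct_tr,dct_co Delta-Ct values (CT_target - CT_ref) for the
#'   treatment and control condition; vectors are averaged.
#' @return Fold change \eqn{2^{-(\overline{\Delta C_T}_{Tr} -
#'   \overline{\Delta C_T}_{Co})}}.
#' @examples
#' livak_fc(3, 5) # 4
#' @export
livak_fc <- function(dct_tr, dct_co) {
  fold_change(mean(dct_tr), mean(dct_co))
}

#' Back-transformed standard-error bounds
#'
#' qPCR fold changes and relative expressions are lognormally distributed, so
#' standard errors are computed on the log2 (weighted delta-Ct) scale and
#' back-transformed around the point estimate:
#' \deqn{Lower.se = 2^{\log_2(FC) - se},\quad Upper.se = 2^{\log_2(FC) + se}.}
#' The bounds are multiplicatively symmetric: `upper / center == center / lower`.
#'
#' @param center Fold change or relative expression (must be positive).
#' @param se_log2 Standard error on the log2 scale (non-negative).
#' @return A tibble with columns `lower_se` and `upper_se`.
#' @examples
#' se_backtransform(4.0185, 0.2193)
#' @export
se_backtransform <- function(center, se_log2) {
  if (any(center <= 0) || !all(is.finite(center))) {
    abort("`center` must be positive and finite.")
  }
  if (any(se_log2 < 0) || !all(is.finite(se_log2))) {
    abort("`se_log2` must be non-negative and finite.")
  }
  tibble(
    lower_se = 2^(log2(center) - se_log2),
    upper_se = 2^(log2(center) + se_log2)
  )
}

#' Back-transformed confidence limits
#'
#' Two-sided t-based confidence limits on the log2 scale, back-transformed to
#' the fold-change / relative-expression scale:
#' \deqn{2^{\log_2(center) \mp t_{df,\,1-(1-level)/2}\; se}.}
#' A t rather than normal quantile is used because qPCR designs are
#' small-sample.
#'
#' @inheritParams se_backtransform
#' @param df Degrees of freedom for the t quantile (>= 1); `Inf` gives the
#'   normal quantile.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `lcl` and `ucl`.
#' @examples
#' ci_backtransform(4, 0.25, df = 4)
#' @export
ci_backtransform <- function(center, se_log2, df, level = 0.95) {
  if (any(center <= 0) || !all(is.finite(center))) {
    abort("`center` must be positive and finite.")
  }
  if (any(se_log2 < 0)) abort("`se_log2` must be non-negative.")
  if (any(df < 1) || any(is.na(df))) abort("`df` must be >= 1.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  tcrit <- qt(1 - (1 - level) / 2, df)
  tibble(
    lcl = 2^(log2(center) - tcrit * se_log2),
    ucl = 2^(log2(center) + tcrit * se_log2)
  )
}

# Significance marks used throughout the result tables:
# p <= 0.01 "**", <= 0.05 "*", <= 0.1 ".", else "".
sig_marks <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    p <= 0.1 ~ ".",
    .default = ""
  )
}

#' Adjust p-values across tests
#'
#' Thin validated wrapper around [stats::p.adjust()]; the package default is
#' Benjamini-Hochberg (`"BH"`) wherever several genes or contrasts are tested
#' together.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Adjustment method; any value accepted by
#'   [stats::p.adjust()], or `"none"` for the identity.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03)) # all 0.03 under BH
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = method)
}
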