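# Amplification-efficiency estimation from dilution-series standard curves.
# Ct regressed on log10(dilution); E = 10^(-1/slope), so a slope of -3.3219
# corresponds to E = 2 (100% efficiency, perfect per-cycle doubling).

#' Fit a standard curve for one gene
#'
#' Ordinary least squares of Ct on log10(dilution). The amplification
#' efficiency is `E = 10^(-1 / slope)`; percent efficiency is `(E - 1) * 100`,
#' so a slope of -3.3219 gives E = 2 and 100%.
#'
#' @param dilution Dilution values; see `dilution_scale`.
#' @param ct Threshold cycles, same length as `dilution`.
#' @param gene Label attached to the result row.
#' @param dilution_scale How to interpret `dilution`: `"auto"` (default)
#'   treats positive values as dilution factors or quantities (both are
#'   log10-transformed) and values containing non-positives as already being
#'   log10 quantities; `"fraction"`/`"quantity"` force the log10 transform;
#'   `"log10"` uses the values as-is.
#' @return A one-row tibble of class `qpcr_efficiency` with columns `gene`,
#'   `slope` (cycles per log10 dilution), `intercept`, `r_squared`,
#'   `efficiency` (E, amplification-factor scale) and `percent_efficiency`.
#' @examples
#' fit_standard_curve(c(1, 0.1, 0.01), c(20, 23.3219, 26.6439))
#' @export
fit_standard_curve <- function(dilution, ct, gene = "gene",
                               dilution_scale = c("auto", "fraction",
                                                  "quantity", "log10")) {
  dilution_scale <- match.arg(dilution_scale)
  if (length(dilution) != length(ct)) {
    abort("`dilution` and `ct` must have the same length.")
  }
  if (length(dilution) < 3) {
    abort("A standard curve needs at least 3 points.")
  }
  x <- dilution_to_log10(dilution, dilution_scale)
  if (length(unique(x)) < 2) {
    abort("All dilutions are equal; the standard-curve fit is singular.")
  }
  fit <- lm(ct ~ x)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn(sprintf("Standard curve for %s has a non-negative slope (%.4f); Ct should increase as template is diluted. Check the data.",
                 gene, slope))
  }
  # summary.lm warns on exact collinear points; a perfect standard curve is
  # legitimate here (noiseless calibration data)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    tibble(
      gene = gene,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope),
      percent_efficiency = (10^(-1 / slope) - 1) * 100
    ),
    class = c("qpcr_efficiency", class(tibble())),
    fit = fit
  )
}

dilution_to_log10 <- function(dilution, scale) {
  if (!all(is.finite(dilution))) abort("Dilution values must be finite.")
  if (scale == "log10") return(dilution)
  if (scale %in% c("fraction", "quantity") || all(dilution > 0)) {
    return(log10(dilution))
  }
  # non-positive values can only be log10 quantities already
  dilution
}

#' Amplification-efficiency analysis of a dilution-series table
#'
#' Fits one standard curve per gene Ct column of an efficiency-layout table
#' (see [qpcr_table()]), returning slope, intercept, R-squared, E and percent
#' efficiency per gene, plus pairwise statistical comparisons of the slopes
#' (see [compare_slopes()]) when more than one gene is present.
#'
#' @param data An efficiency-layout `qpcr_tbl` or a data frame whose first
#'   column is the dilution and remaining columns are per-gene Ct values.
#' @inheritParams fit_standard_curve
#' @return A `qpcr_efficiency` tibble with one row per gene; the pairwise
#'   slope comparison table is attached as attribute `"slope_comparison"`
#'   (also accessible with [compare_slopes()]).
#' @examples
#' d <- simulate_dilution(c(a = 2, b = 1.9), dilutions = c(1, 0.1, 0.01))
#' qpcr_efficiency(d)
#' @export
qpcr_efficiency <- function(data, dilution_scale = c("auto", "fraction",
                                                     "quantity", "log10")) {
  dilution_scale <- match.arg(dilution_scale)
  if (!inherits(data, "qpcr_tbl") || qpcr_meta(data)$layout != "efficiency") {
    data <- qpcr_table(data, "efficiency")
  }
  genes <- qpcr_meta(data)$genes
  fits <- purrr::map(genes, ~ fit_standard_curve(
    data$dilution, data[[.x]], gene = .x, dilution_scale = dilution_scale
  ))
  out <- dplyr::bind_rows(fits)
  comparison <- if (length(genes) >= 2) {
    compare_slopes_impl(data, genes, dilution_scale)
  } else {
    NULL
  }
  structure(out,
            class = c("qpcr_efficiency", class(tibble())),
            slope_comparison = comparison,
            data = data, dilution_scale = dilution_scale)
}

#' Pairwise comparison of standard-curve slopes
#'
#' Tests whether genes amplify with significantly different efficiencies by
#' fitting the joint model `Ct ~ log10(dilution) * gene` and extracting the
#' pairwise slope (interaction) contrasts, which pool the residual error
#' across genes. p-values are Benjamini-Hochberg adjusted when more than one
#' pair is tested.
#'
#' @param data An efficiency-layout table with at least two gene Ct columns,
#'   or a `qpcr_efficiency` result (its comparison table is returned).
#' @inheritParams fit_standard_curve
#' @return A tibble with one row per gene pair: `gene_pair`,
#'   `slope_difference`, `se`, `df`, `p_value`, `p_adj`.
#' @export
compare_slopes <- function(data, dilution_scale = c("auto", "fraction",
                                                    "quantity", "log10")) {
  dilution_scale <- match.arg(dilution_scale)
  if (inherits(data, "qpcr_efficiency")) {
    cmp <- attr(data, "slope_comparison")
    if (is.null(cmp)) abort("Slope comparison needs at least two genes.")
    return(cmp)
  }
  if (!inherits(data, "qpcr_tbl") || qpcr_meta(data)$layout != "efficiency") {
    data <- qpcr_table(data, "efficiency")
  }
  genes <- qpcr_meta(data)$genes
  if (length(genes) < 2) abort("Slope comparison needs at least two genes.")
  compare_slopes_impl(data, genes, dilution_scale)
}

compare_slopes_impl <- function(data, genes, dilution_scale) {
  long <- data |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(genes), names_to = "gene",
                        values_to = "ct") |>
    dplyr::mutate(
      log_dil = dilution_to_log10(.data$dilution, dilution_scale),
      gene = factor(.data$gene, levels = genes)
    )
  fit <- lm(ct ~ log_dil * gene, data = long)
  trends <- emmeans::emtrends(fit, "gene", var = "log_dil")
  prs <- summary(emmeans::contrast(trends, "pairwise"), adjust = "none",
                 infer = c(FALSE, TRUE))
  tibble(
    gene_pair = gsub(" - ", " vs ", prs$contrast),
    slope_difference = prs$estimate,
    se = prs$SE,
    df = prs$df,
    p_value = prs$p.value,
    p_adj = if (nrow(prs) > 1) adjust_pvalues(prs$p.value, "BH") else prs$p.value
  )
}

#' Standard-curve plot data
#'
#' Deterministic plottable representation of an efficiency analysis: observed
#' points, fitted-line endpoints, and per-gene annotation strings reporting
#' slope, E and R-squared (4 significant figures). [autoplot.qpcr_efficiency()]
#' renders exactly this structure.
#'
#' @param results A `qpcr_efficiency` result from [qpcr_efficiency()].
#' @return A list with tibbles `points` (gene, log_dilution, ct), `lines`
#'   (gene, log_dilution, ct_fitted) and `annotations` (gene, label).
#' @export
standard_curve_plot_data <- function(results) {
  if (!inherits(results, "qpcr_efficiency") || !nrow(results)) {
    abort("`results` must be a non-empty qpcr_efficiency object.")
  }
  data <- attr(results, "data")
  if (is.null(data)) {
    abort("This qpcr_efficiency object carries no source data; build it with qpcr_efficiency().")
  }
  scale <- attr(results, "dilution_scale") %||% "auto"
  genes <- results$gene
  x <- dilution_to_log10(data$dilution, scale)
  points <- purrr::map_dfr(genes, function(g) {
    tibble(gene = g, log_dilution = x, ct = data[[g]])
  })
  lines <- purrr::map_dfr(seq_len(nrow(results)), function(i) {
    xs <- range(x)
    tibble(gene = genes[i], log_dilution = xs,
           ct_fitted = results$intercept[i] + results$slope[i] * xs)
  })
  annotations <- tibble(
    gene = genes,
    label = sprintf("%s: slope = %.4g, E = %.4g, R² = %.4g",
                    genes, results$slope, results$efficiency,
                    results$r_squared)
  )
  list(points = points, lines = lines, annotations = annotations)
}
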