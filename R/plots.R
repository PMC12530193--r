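# Publication-style bar plots. Every plot is a pure rendering of a small
# plottable structure (bar heights, whisker ends, annotations) that is
# exposed and tested on its own; the error-bar choice changes whiskers
# only, never bar heights.

#' Plot data behind a fold-change bar plot
#'
#' @param results A `qpcr_fc` result ([qpcr_ttest()], [qpcr_anova_fc()],
#'   [qpcr_repeated()], [qpcr_means()]).
#' @param error_bar `"se"` for back-transformed standard-error whiskers
#'   (`lower_se`/`upper_se`), `"ci"` for confidence limits (`lcl`/`ucl`).
#' @return A tibble with `label`, `height`, `ymin`, `ymax`, `sig`.
#' @export
fc_plot_data <- function(results, error_bar = c("se", "ci")) {
  error_bar <- match.arg(error_bar)
  if (is.null(results) || !nrow(results)) abort("`results` is empty.")
  label <- results[["gene"]] %||% results[["contrast"]]
  tibble(
    label = factor(label, levels = unique(label)),
    height = results$fc,
    ymin = if (error_bar == "se") results$lower_se else results$lcl,
    ymax = if (error_bar == "se") results$upper_se else results$ucl,
    sig = results$sig %||% ""
  )
}

#' Plot data behind a relative-expression bar plot
#'
#' @param results A `qpcr_re` result from [qpcr_anova_re()].
#' @param error_bar `"se"` (back-transformed SE bounds), `"ci"` (confidence
#'   limits) or `"sd"` (replicate-scale standard deviation, clipped at 0).
#' @return A tibble with the factor columns, `label`, `height`, `ymin`,
#'   `ymax`, `letters`.
#' @export
re_plot_data <- function(results, error_bar = c("se", "ci", "sd")) {
  error_bar <- match.arg(error_bar)
  if (is.null(results) || !nrow(results)) abort("`results` is empty.")
  fac_cols <- attr(results, "factor_cols") %||% character()
  if (length(fac_cols) > 3) abort("At most 3 factors can be displayed.")
  label <- do.call(paste, c(lapply(results[fac_cols], as.character), sep = ":"))
  bounds <- switch(error_bar,
    se = list(results$lower_se, results$upper_se),
    ci = list(results$lcl, results$ucl),
    sd = list(pmax(results$re - results$sd, 0), results$re + results$sd)
  )
  dplyr::bind_cols(
    as_tibble(results[fac_cols]),
    tibble(
      label = factor(label, levels = unique(label)),
      height = results$re,
      ymin = bounds[[1]], ymax = bounds[[2]],
      letters = results$letters
    )
  )
}

#' Fold-change bar plot
#'
#' One bar per gene or contrast at the fold-change estimate, whiskers at the
#' chosen error bounds, significance marks above the bars and a horizontal
#' guide at FC = 1.
#'
#' @inheritParams fc_plot_data
#' @param fill Bar fill colour.
#' @param ylab Y-axis label.
#' @param file Optional output path (png/svg/pdf chosen by extension); when
#'   given the plot is also written to disk.
#' @param width,height,dpi Device settings used when `file` is given.
#' @return A ggplot object (invisibly returns `file` when writing).
#' @export
plot_fc_bars <- function(results, error_bar = c("se", "ci"),
                         fill = "grey35", ylab = "Fold change",
                         file = NULL, width = 5, height = 4, dpi = 300) {
  pd <- fc_plot_data(results, error_bar)
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$label, y = .data$height)) +
    ggplot2::geom_col(fill = fill, width = 0.65) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(y = .data$ymax, label = .data$sig),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
  maybe_save(p, file, width, height, dpi)
}

#' Relative-expression bar plot
#'
#' Bars at the relative-expression estimates, grouped/dodged by up to three
#' factors, with compact-letter-display letters above the whiskers.
#'
#' @inheritParams re_plot_data
#' @inheritParams plot_fc_bars
#' @return A ggplot object (invisibly returns `file` when writing).
#' @export
plot_re_bars <- function(results, error_bar = c("se", "ci", "sd"),
                         ylab = "Relative expression",
                         file = NULL, width = 5, height = 4, dpi = 300) {
  pd <- re_plot_data(results, error_bar)
  fac_cols <- attr(results, "factor_cols") %||% character()
  p <- if (length(fac_cols) >= 2) {
    ggplot2::ggplot(pd, ggplot2::aes(x = .data[[fac_cols[1]]],
                                     y = .data$height,
                                     fill = .data[[fac_cols[2]]])) +
      ggplot2::geom_col(position = ggplot2::position_dodge(0.8),
                        width = 0.7) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
        position = ggplot2::position_dodge(0.8), width = 0.15, na.rm = TRUE
      ) +
      ggplot2::geom_text(
        ggplot2::aes(y = .data$ymax, label = .data$letters),
        position = ggplot2::position_dodge(0.8), vjust = -0.4, na.rm = TRUE
      ) +
      (if (length(fac_cols) == 3) {
        ggplot2::facet_wrap(stats::as.formula(paste("~", fac_cols[3])))
      } else NULL)
  } else {
    ggplot2::ggplot(pd, ggplot2::aes(x = .data$label, y = .data$height)) +
      ggplot2::geom_col(fill = "grey35", width = 0.65) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin,
                                          ymax = .data$ymax),
                             width = 0.15, na.rm = TRUE) +
      ggplot2::geom_text(ggplot2::aes(y = .data$ymax, label = .data$letters),
                         vjust = -0.4, na.rm = TRUE)
  }
  p <- p + ggplot2::labs(x = NULL, y = ylab) + ggplot2::theme_classic()
  maybe_save(p, file, width, height, dpi)
}

maybe_save <- function(p, file, width, height, dpi) {
  if (!is.null(file)) {
    ggplot2::ggsave(file, plot = p, width = width, height = height,
                    dpi = dpi)
    return(invisible(file))
  }
  p
}

#' @rdname plot_fc_bars
#' @param object A `qpcr_fc` result.
#' @param ... Passed to [plot_fc_bars()].
#' @export
autoplot.qpcr_fc <- function(object, ...) plot_fc_bars(object, ...)

#' @rdname plot_re_bars
#' @param object A `qpcr_re` result.
#' @param ... Passed to [plot_re_bars()].
#' @export
autoplot.qpcr_re <- function(object, ...) plot_re_bars(object, ...)

#' Standard-curve plot
#'
#' Observed Ct against log10 dilution with the fitted regression line per
#' gene and an annotation reporting slope, E and R-squared.
#'
#' @param object A `qpcr_efficiency` result from [qpcr_efficiency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qpcr_efficiency <- function(object, ...) {
  pd <- standard_curve_plot_data(object)
  ggplot2::ggplot(pd$points,
                  ggplot2::aes(x = .data$log_dilution, y = .data$ct,
                               colour = .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pd$lines,
                       ggplot2::aes(y = .data$ct_fitted)) +
    ggplot2::labs(x = "log10(dilution)", y = "Ct", colour = NULL,
                  subtitle = paste(pd$annotations$label, collapse = "\n")) +
    ggplot2::theme_classic()
}
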