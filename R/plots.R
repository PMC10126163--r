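#' Plot an ALS profile
#'
#' Log-log plot of ring-averaged scattered intensity against the wave
#' vector q.
#'
#' @param object An `als_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.als_profile <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$q > 0 & d$s > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$q, .data$s)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (rad/µm)", y = "ring-averaged intensity (a.u.)",
                  title = "Angular light-scattering profile")
}

#' Plot a density-correlation curve, optionally with fit and window
#'
#' @param object A `correlation_curve`.
#' @param fit Optional `fractal_fit` whose power law is overlaid.
#' @param fw Optional `fractal_window` shaded on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_curve <- function(object, fit = NULL, fw = NULL, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$r, .data$c)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "correlation distance r (µm)",
                  y = expression(C[rho](r)),
                  title = "Density-correlation curve")
  if (!is.null(fw)) {
    p <- p + ggplot2::annotate("rect", xmin = fw$r_min, xmax = fw$r_max,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  if (!is.null(fit)) {
    line <- tibble::tibble(
      r = c(fit$r_lo, fit$r_hi),
      c = 10^(fit$intercept + fit$slope * log10(c(fit$r_lo, fit$r_hi)))
    )
    p <- p + ggplot2::geom_line(data = line, colour = "red")
  }
  p
}

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUROC = %.3f)", object$auroc))
}

#' Z-scored profile heatmap of a feature table
#'
#' Cells-by-features heatmap of z-scored values, the standard profile view
#' of a cohort (cells ordered by label).
#'
#' @param data A feature tibble with a label column.
#' @param label_col Name of the label column.
#' @param feature_cols Tidy-select of features (default as in
#'   [zscore_features()]).
#' @return A ggplot.
#' @export
plot_profile_heatmap <- function(data, label_col = "label",
                                 feature_cols = NULL) {
  z <- zscore_features(data, {{ feature_cols }})
  cols <- resolve_feature_cols(z, rlang::enquo(feature_cols))
  z <- z[order(z[[label_col]]), ]
  z$.cell <- seq_len(nrow(z))
  long <- tidyr::pivot_longer(z[c(".cell", label_col, cols)],
                              dplyr::all_of(cols),
                              names_to = "feature", values_to = "zscore")
  long$feature <- factor(long$feature, levels = rev(cols))
  ggplot2::ggplot(long, ggplot2::aes(.data$.cell, .data$feature,
                                     fill = .data$zscore)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-3, 3), oob = scales_squish) +
    ggplot2::labs(x = "cell", y = NULL, fill = "z")
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(-3, 3)) {
  pmin(pmax(x, range[1]), range[2])
}
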