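#' Tidy a fractal fit
#'
#' @param x A `fractal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`term`, `estimate`).
#' @export
tidy.fractal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "alpha", "fd"),
    estimate = c(x$intercept, x$slope, x$alpha, x$fd)
  )
}

#' @rdname tidy.fractal_fit
#' @return For `glance()`: a one-row model summary (`fd`, `alpha`, `mse`,
#'   `r_lo`, `r_hi`, `n_bins`).
#' @export
glance.fractal_fit <- function(x, ...) {
  tibble::tibble(fd = x$fd, alpha = x$alpha, mse = x$mse,
                 r_lo = x$r_lo, r_hi = x$r_hi, n_bins = x$n_bins)
}

#' Tidy an ROC result
#'
#' @param x A `roc_result` from [auroc()].
#' @param ... Unused.
#' @return The ROC curve as a tibble (`threshold`, `fpr`, `tpr`).
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n_thresholds = length(x$thresholds) - 1)
}

#' Tidy a linear one-versus-all classifier
#'
#' @param x An `ova_classifier` from [linear_ova_classifier()].
#' @param ... Unused.
#' @return A tibble of classifier weights (`term`, `estimate`).
#' @export
tidy.ova_classifier <- function(x, ...) {
  tibble::tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @rdname tidy.ova_classifier
#' @export
glance.ova_classifier <- function(x, ...) {
  tibble::tibble(positive = x$positive, auroc = x$roc$auroc,
                 n_cells = length(x$scores),
                 n_features = length(x$weights) - 1)
}
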