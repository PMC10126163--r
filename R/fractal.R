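#' Fit the fractal power law to a correlation curve
#'
#' Ordinary least squares of log10(c) on log10(r) over `[r_lo, r_hi]`.
#' The fractal dimension follows from the decay exponent alpha of
#' C_rho(r) ~ r^(-alpha) as FD = 3 - alpha; the mean squared log-log
#' residual measures how well power-law (fractal) scaling holds over the
#' probed scales.
#'
#' @param curve A `correlation_curve` from [density_correlation()] (any
#'   data frame with positive `r` and `c` columns works).
#' @param r_lo,r_hi Fit range in micrometres; at least 3 curve bins must
#'   fall inside it.
#' @return A list of class `fractal_fit` with `alpha`, `fd = 3 - alpha`,
#'   `mse`, `slope`, `intercept`, `r_lo`, `r_hi`, `n_bins`.
#' @export
fit_overall_fd <- function(curve, r_lo, r_hi) {
  if (!is.numeric(r_lo) || !is.numeric(r_hi) || r_lo >= r_hi) {
    abort("need r_lo < r_hi", class = "fractometry_parameter_error")
  }
  d <- curve[curve$r >= r_lo & curve$r <= r_hi & curve$c > 0, , drop = FALSE]
  if (nrow(d) < 3) {
    abort("fewer than 3 usable correlation bins in the fit range",
          class = "fractometry_insufficient_data_error")
  }
  fit <- lm(log10(c) ~ log10(r), data = d)
  res <- stats::residuals(fit)
  slope <- unname(coef(fit)[2])
  structure(list(
    alpha = -slope, fd = 3 + slope, mse = mean(res^2),
    slope = slope, intercept = unname(coef(fit)[1]),
    r_lo = r_lo, r_hi = r_hi, n_bins = nrow(d)
  ), class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat("<fractal_fit> FD = ", signif(x$fd, 4), " (alpha = ", signif(x$alpha, 4),
      "), MSE = ", signif(x$mse, 3), ", ", x$n_bins, " bins in [",
      signif(x$r_lo, 3), ", ", signif(x$r_hi, 3), "] um\n", sep = "")
  invisible(x)
}

# Centered (2w+1)-bin local log-log slopes; NA where the window is clipped.
local_slopes <- function(log_r, log_c, w) {
  n <- length(log_r)
  s <- rep(NA_real_, n)
  if (n < 2 * w + 1) return(s)
  for (i in (w + 1):(n - w)) {
    idx <- (i - w):(i + w)
    x <- log_r[idx]; y <- log_c[idx]
    s[i] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  s
}

#' Detect the fractal window of a correlation curve
#'
#' Cells are self-similar only over a limited range of length scales; the
#' fractal window (FW) is the correlation-distance interval with the most
#' prominent downward slope. Local slopes from centred (2w+1)-bin
#' regressions are compared with the overall fit: bins whose local slope is
#' at least as steep as the overall slope are eligible (the flat short- and
#' long-distance segments are thereby excluded), and the contiguous eligible
#' run maximising the prominence integral
#' sum((s_overall - s(r)) * dlog10(r)) is selected. Ties are broken toward
#' the longer run, then the smaller `r_min`.
#'
#' @param curve A `correlation_curve`.
#' @param overall The [fit_overall_fd()] result for the analysis range.
#' @param w Local-regression half-width in bins.
#' @param min_bins,min_decades Minimum admissible window length: a run must
#'   span at least `min_bins` bins and at least `min_decades` decades.
#' @return A list of class `fractal_window` with `r_min`, `r_max`,
#'   `width_decades`, `prominence`, and `fallback` (TRUE when no eligible
#'   run exists and the whole analysis range is returned).
#' @export
detect_fractal_window <- function(curve, overall, w = 2L,
                                  min_bins = 5L, min_decades = 0.3) {
  d <- curve[curve$r >= overall$r_lo & curve$r <= overall$r_hi & curve$c > 0, ,
             drop = FALSE]
  n <- nrow(d)
  fallback <- structure(list(
    r_min = overall$r_lo, r_max = overall$r_hi,
    width_decades = log10(overall$r_hi / overall$r_lo),
    prominence = 0, fallback = TRUE
  ), class = "fractal_window")
  if (n < 2 * w + 1) return(fallback)
  lr <- log10(d$r); lc <- log10(d$c)
  s <- local_slopes(lr, lc, w)
  s_overall <- overall$slope
  tol <- 1e-9 * (1 + abs(s_overall))
  eligible <- !is.na(s) & s <= s_overall + tol
  # per-bin log-width (centred differences, one-sided at the ends)
  dl <- numeric(n)
  if (n >= 2) {
    dl[1] <- lr[2] - lr[1]
    dl[n] <- lr[n] - lr[n - 1]
    if (n > 2) dl[2:(n - 1)] <- (lr[3:n] - lr[1:(n - 2)]) / 2
  }
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 - i0 + 1 < min_bins) next
    if (lr[i1] - lr[i0] < min_decades) next
    prom <- sum((s_overall - s[i0:i1]) * dl[i0:i1])
    cand <- list(i0 = i0, i1 = i1, prom = prom, len = i1 - i0 + 1)
    if (is.null(best)) { best <- cand; next }
    rel <- abs(cand$prom - best$prom) <= 1e-12 * (1 + abs(best$prom))
    if ((!rel && cand$prom > best$prom) ||
        (rel && (cand$len > best$len ||
                 (cand$len == best$len && cand$i0 < best$i0)))) {
      best <- cand
    }
  }
  if (is.null(best)) return(fallback)
  structure(list(
    r_min = d$r[best$i0], r_max = d$r[best$i1],
    width_decades = lr[best$i1] - lr[best$i0],
    prominence = best$prom, fallback = FALSE
  ), class = "fractal_window")
}

#' @export
print.fractal_window <- function(x, ...) {
  cat("<fractal_window> [", signif(x$r_min, 4), ", ", signif(x$r_max, 4),
      "] um (", signif(x$width_decades, 3), " decades, prominence ",
      signif(x$prominence, 3), if (x$fallback) ", fallback" else "", ")\n",
      sep = "")
  invisible(x)
}

#' Fractal-dimension fit restricted to the fractal window
#'
#' @param curve A `correlation_curve`.
#' @param fw A [detect_fractal_window()] result.
#' @return A `fractal_fit` over `[fw$r_min, fw$r_max]`.
#' @export
fit_fd_within_window <- function(curve, fw) {
  fit_overall_fd(curve, fw$r_min, fw$r_max)
}

#' Summary statistics of an ALS profile
#'
#' Log-domain moments (mean, SD, skewness, excess kurtosis of log10 s), the
#' log-log slope of s versus q, and the fractions of total scattered
#' intensity falling in the low/mid/high q bands split at `q_cuts`.
#' The zero-q (DC) bin is excluded; intensities are floored at
#' 1e-12 * max(s) before taking logs.
#'
#' @param als An `als_profile` from [angular_profile()].
#' @param q_cuts Two increasing thresholds (rad/um); default the 1/3 and
#'   2/3 quantiles of the retained q grid.
#' @return A named list of 8 scalars: `als_log_mean`, `als_log_sd`,
#'   `als_log_skew`, `als_log_kurt`, `als_slope`, `als_frac_lowq`,
#'   `als_frac_midq`, `als_frac_highq`.
#' @export
als_statistics <- function(als, q_cuts = NULL) {
  d <- als[als$q > 0, , drop = FALSE]
  if (nrow(d) < 8) {
    abort("fewer than 8 ALS bins", class = "fractometry_insufficient_data_error")
  }
  if (is.null(q_cuts)) {
    q_cuts <- unname(quantile(d$q, c(1, 2) / 3))
  }
  if (length(q_cuts) != 2 || q_cuts[1] >= q_cuts[2]) {
    abort("q_cuts must be two increasing thresholds",
          class = "fractometry_parameter_error")
  }
  s <- pmax(d$s, 1e-12 * max(d$s, 1e-300))
  ls <- log10(s)
  m <- mean(ls)
  v <- mean((ls - m)^2)
  sdv <- sqrt(v)
  skew <- if (sdv > 0) mean((ls - m)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((ls - m)^4) / sdv^4 - 3 else 0
  lq <- log10(d$q)
  slope <- sum((lq - mean(lq)) * (ls - m)) / sum((lq - mean(lq))^2)
  tot <- sum(s)
  list(
    als_log_mean = m, als_log_sd = sdv, als_log_skew = skew,
    als_log_kurt = kurt, als_slope = slope,
    als_frac_lowq = sum(s[d$q <= q_cuts[1]]) / tot,
    als_frac_midq = sum(s[d$q > q_cuts[1] & d$q <= q_cuts[2]]) / tot,
    als_frac_highq = sum(s[d$q > q_cuts[2]]) / tot
  )
}

#' Names of the 17 fractal/ALS features, in catalog order
#'
#' Version 1 of the catalog: five fractal-fit features named in the field
#' (FD; overall-fit MSE; FD within the fractal window; FW width; FD width),
#' the window geometry and fit diagnostics, and eight ALS-profile
#' statistics.
#'
#' @return Character vector of length 17.
#' @export
fractal_feature_names <- function() {
  c("fd", "fd_mse2", "fd_with_fw", "fd_fw_mse", "fw_width", "fw_r_min",
    "fw_r_max", "fd_width", "fw_prominence", "als_log_mean", "als_log_sd",
    "als_log_skew", "als_log_kurt", "als_slope", "als_frac_lowq",
    "als_frac_midq", "als_frac_highq")
}

#' Full fractal/ALS feature profile of a complex field
#'
#' Runs the Fourier-domain chain on one cell: far-field propagation, ALS
#' ring averaging, density-correlation curve, overall power-law fit,
#' fractal-window detection and within-window fit, and ALS statistics —
#' then assembles the 17-feature catalog (see [fractal_feature_names()]).
#' The default analysis range is `r_lo = 2 * pixel_um` (resolution
#' criterion) to `r_hi =` the equivalent cell radius from `mask`, or a
#' quarter of the field of view when no mask is given.
#'
#' @param field A [complex_field()].
#' @param mask Optional [segment_cell()] result bounding the analysis range.
#' @param pad_factor,window Passed to [far_field_pattern()].
#' @param fw_halfwidth,fw_min_bins,fw_min_decades Passed to
#'   [detect_fractal_window()].
#' @param q_cuts Passed to [als_statistics()].
#' @param cell_id Optional identifier prepended to the output row.
#' @return A one-row tibble with 17 feature columns (preceded by `cell_id`
#'   when given); attribute `catalog_version` = 1.
#' @export
fractal_profile <- function(field, mask = NULL, pad_factor = 1L,
                            window = "none", fw_halfwidth = 2L,
                            fw_min_bins = 5L, fw_min_decades = 0.3,
                            q_cuts = NULL, cell_id = NULL) {
  p <- far_field_pattern(field, pad_factor = pad_factor, window = window)
  als <- angular_profile(p)
  curve <- density_correlation(p)
  r_lo <- 2 * field$pixel_um
  r_hi <- if (!is.null(mask)) mask$equivalent_radius_um else
    min(dim(field$amplitude)) * field$pixel_um / 4
  overall <- fit_overall_fd(curve, r_lo, r_hi)
  fw <- detect_fractal_window(curve, overall, w = fw_halfwidth,
                              min_bins = fw_min_bins,
                              min_decades = fw_min_decades)
  inwin <- fit_fd_within_window(curve, fw)
  stats8 <- als_statistics(als, q_cuts)
  row <- tibble::tibble(
    fd = overall$fd, fd_mse2 = overall$mse,
    fd_with_fw = inwin$fd, fd_fw_mse = inwin$mse,
    fw_width = fw$width_decades, fw_r_min = fw$r_min, fw_r_max = fw$r_max,
    fd_width = abs(overall$fd - inwin$fd), fw_prominence = fw$prominence,
    !!!stats8
  )
  if (!is.null(cell_id)) {
    row <- dplyr::bind_cols(tibble::tibble(cell_id = cell_id), row)
  }
  attr(row, "catalog_version") <- 1L
  attr(row, "fw_fallback") <- fw$fallback
  attr(row, "degenerate") <- overall$mse == 0 && abs(overall$alpha) < 1e-12
  row
}
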