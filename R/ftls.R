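#' Far-field scattering pattern by Fourier-transform light scattering
#'
#' Numerically propagates the measured complex field to the far field: the
#' scattered field is the centred 2D Fourier transform of
#' A(x,y) * exp(i * phi(x,y)), and the pattern is its squared modulus.
#' Spatial-frequency axes are in rad/um, derived from the pixel pitch and
#' the (optionally zero-padded) grid size. The unnormalised transform
#' convention means sum(|E|^2) == sum(intensity) / N_pixels (Parseval).
#'
#' @param field A [complex_field()].
#' @param pad_factor Integer >= 1; zero-padding factor refining the
#'   frequency sampling (total pattern energy is unchanged).
#' @param window Apodisation applied before the transform: `"none"` or
#'   `"hann"` (2D separable Hann).
#' @return A list of class `scattering_pattern` with `intensity` matrix,
#'   centred axes `kx_axis`, `ky_axis` (rad/um), `wavelength_um`, `pixel_um`.
#' @export
far_field_pattern <- function(field, pad_factor = 1L, window = c("none", "hann")) {
  window <- match.arg(window)
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) {
    abort("pad_factor must be an integer >= 1",
          class = "fractometry_parameter_error")
  }
  e <- field_matrix(field)
  if (window == "hann") {
    hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(e)) - 1) / (nrow(e) - 1))
    hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(e)) - 1) / (ncol(e) - 1))
    e <- e * outer(hr, hc)
  }
  e <- pad_zero(e, pad_factor)
  s <- fftshift_mat(fft2(e))
  structure(list(
    intensity = Mod(s)^2,
    kx_axis = 2 * pi * sort(fft_freq(ncol(e))) / field$pixel_um,
    ky_axis = 2 * pi * sort(fft_freq(nrow(e))) / field$pixel_um,
    wavelength_um = field$wavelength_um,
    pixel_um = field$pixel_um
  ), class = "scattering_pattern")
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat("<scattering_pattern> ", nrow(x$intensity), "x", ncol(x$intensity),
      " bins, k range +/-", signif(max(abs(x$kx_axis)), 4), " rad/um\n", sep = "")
  invisible(x)
}

#' Angular light-scattering (ALS) profile of a scattering pattern
#'
#' Averages the scattered intensity over rings of constant wave vector
#' q = (4 * pi / lambda) * sin(theta / 2), where theta is the polar
#' scattering angle recovered from the radial spatial frequency
#' (k_r = 2 * pi * sin(theta) / lambda). Evanescent bins (sin(theta) > 1)
#' are discarded; ring bins are one frequency pixel wide and empty bins are
#' dropped.
#'
#' @param p A `scattering_pattern` from [far_field_pattern()].
#' @return A tibble of class `als_profile` with columns `q` (rad/um,
#'   strictly increasing), `theta` (radians), `s` (ring-averaged intensity)
#'   and `counts`; attributes `wavelength_um` and `bin_width`.
#' @export
angular_profile <- function(p) {
  if (!inherits(p, "scattering_pattern")) {
    abort("`p` must be a scattering_pattern",
          class = "fractometry_structural_error")
  }
  lam <- p$wavelength_um
  kr <- sqrt(outer(p$ky_axis^2, p$kx_axis^2, `+`))
  sin_theta <- kr * lam / (2 * pi)
  keep <- sin_theta <= 1
  if (!any(keep)) {
    abort("no propagating spatial frequencies in the pattern",
          class = "fractometry_degenerate_error")
  }
  theta <- asin(sin_theta[keep])
  q <- 4 * pi / lam * sin(theta / 2)
  dk <- 2 * pi / (ncol(p$intensity) * p$pixel_um)  # one frequency pixel
  rb <- radial_average(q, p$intensity[keep], dk)
  out <- tibble::tibble(
    q = rb$radius,
    theta = 2 * asin(pmin(rb$radius * lam / (4 * pi), 1)),
    s = rb$mean,
    counts = rb$counts
  )
  structure(out, class = c("als_profile", class(out)),
            wavelength_um = lam, bin_width = dk)
}

#' Density-correlation curve from a scattering pattern
#'
#' The real-space density-density correlation is obtained from the
#' scattering intensity through the Wiener-Khinchin relation: the inverse
#' 2D transform of the intensity pattern is the (complex) spatial
#' autocorrelation of the field on the image grid. Its modulus is radially
#' averaged over lag radius, normalised by the zero-lag value, and retained
#' between one pixel and half the field of view. For a mass-fractal
#' specimen the curve decays as a power law r^(-alpha) inside the fractal
#' window, which downstream fitting turns into a fractal dimension.
#'
#' @param p A `scattering_pattern` from [far_field_pattern()].
#' @param mode Realisation of the correlation estimate; only the 2D
#'   Wiener-Khinchin route `"wiener_khinchin_2d"` is defined.
#' @return A tibble of class `correlation_curve` with columns `r` (um,
#'   strictly increasing), `c` (positive, `c = 1` at zero lag before
#'   pruning), `log_r`, `log_c`; attribute `pixel_um`.
#' @export
density_correlation <- function(p, mode = "wiener_khinchin_2d") {
  mode <- match.arg(mode, "wiener_khinchin_2d")
  if (!inherits(p, "scattering_pattern")) {
    abort("`p` must be a scattering_pattern",
          class = "fractometry_structural_error")
  }
  ac <- Mod(ifft2(ifftshift_mat(p$intensity)))
  nr <- nrow(ac); nc <- ncol(ac)
  lx <- matrix(fft_freq(nc) * nc, nr, nc, byrow = TRUE)
  ly <- matrix(fft_freq(nr) * nr, nr, nc)
  r <- p$pixel_um * sqrt(lx^2 + ly^2)
  c0 <- ac[1, 1]
  if (c0 <= 0) {
    abort("zero-energy pattern has no correlation curve",
          class = "fractometry_degenerate_error")
  }
  rb <- radial_average(as.numeric(r), as.numeric(ac) / c0, p$pixel_um)
  fov_half <- min(nr, nc) * p$pixel_um / 2
  rb <- rb[rb$radius >= p$pixel_um & rb$radius <= fov_half & rb$mean > 0, ]
  out <- tibble::tibble(
    r = rb$radius, c = rb$mean,
    log_r = log10(rb$radius), log_c = log10(rb$mean)
  )
  structure(out, class = c("correlation_curve", class(out)),
            pixel_um = p$pixel_um)
}
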