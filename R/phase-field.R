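#' Bundle four knife-edge intensity images and a background frame
#'
#' The knife-edge acquisition half-blocks the beam from the left, right, top
#' and bottom, so that intensity differences between opposite orientations
#' encode the two phase-gradient components of the specimen. A set holds the
#' four intensity images plus a sample-free background frame.
#'
#' @param ix_plus,ix_minus,iy_plus,iy_minus Nonnegative intensity matrices of
#'   one common shape (x-pair cut from left/right, y-pair from top/bottom).
#' @param background Strictly positive background intensity matrix (same
#'   shape), recorded without a specimen.
#' @return An object of class `knife_edge_set`.
#' @export
knife_edge_set <- function(ix_plus, ix_minus, iy_plus, iy_minus, background) {
  stopifnot_same_shape(ix_plus, ix_minus, iy_plus, iy_minus, background)
  imgs <- list(ix_plus = ix_plus, ix_minus = ix_minus,
               iy_plus = iy_plus, iy_minus = iy_minus)
  for (nm in names(imgs)) {
    if (!all(is.finite(imgs[[nm]])) || any(imgs[[nm]] < 0)) {
      abort(paste0("intensity image `", nm, "` must be finite and nonnegative"),
            class = "fractometry_structural_error")
    }
  }
  if (!all(is.finite(background)) || any(background <= 0)) {
    abort("background must be finite and strictly positive",
          class = "fractometry_structural_error")
  }
  structure(c(imgs, list(background = background)), class = "knife_edge_set")
}

#' @export
print.knife_edge_set <- function(x, ...) {
  cat("<knife_edge_set> ", nrow(x$ix_plus), "x", ncol(x$ix_plus),
      " px, background mean ", signif(mean(x$background), 4), "\n", sep = "")
  invisible(x)
}

#' Complex optical field with physical metadata
#'
#' A quantitative-phase measurement E(x, y) = A(x, y) * exp(i * phi(x, y)):
#' the amplitude image is the bright-field contrast, the phase image the
#' optical path delay in radians.
#'
#' @param amplitude Nonnegative amplitude matrix (a.u.).
#' @param phase Finite phase matrix (radians), same shape.
#' @param wavelength_um Illumination wavelength in micrometres.
#' @param pixel_um Pixel pitch in micrometres.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(amplitude, phase, wavelength_um, pixel_um) {
  stopifnot_same_shape(amplitude, phase)
  if (!all(is.finite(amplitude)) || any(amplitude < 0)) {
    abort("amplitude must be finite and nonnegative",
          class = "fractometry_structural_error")
  }
  if (!all(is.finite(phase))) {
    abort("phase must be finite", class = "fractometry_structural_error")
  }
  if (!is.numeric(wavelength_um) || wavelength_um <= 0 ||
      !is.numeric(pixel_um) || pixel_um <= 0) {
    abort("wavelength_um and pixel_um must be positive scalars",
          class = "fractometry_parameter_error")
  }
  structure(list(amplitude = amplitude, phase = phase,
                 wavelength_um = wavelength_um, pixel_um = pixel_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat("<complex_field> ", nrow(x$amplitude), "x", ncol(x$amplitude),
      " px, lambda ", x$wavelength_um, " um, pitch ", x$pixel_um, " um\n",
      "  phase range [", signif(min(x$phase), 4), ", ",
      signif(max(x$phase), 4), "] rad\n", sep = "")
  invisible(x)
}

#' Integration settings for the Fourier phase integrator
#'
#' @param cf Positive calibration factor applied to the integrated phase
#'   (corrects systematic phase deviation of a real instrument; 1 for the
#'   forward model used here).
#' @param pad_factor Integer >= 1; the gradient images are edge-padded to
#'   `pad_factor` times their size before integration to suppress wrap-around
#'   leakage for non-periodic fields, then cropped back.
#' @param dc_policy How the unobservable phase offset is fixed; only
#'   `"zero"` (zero-mean output) is defined.
#' @return A list of class `integration_config`.
#' @export
integration_config <- function(cf = 1, pad_factor = 1L, dc_policy = "zero") {
  if (!is.numeric(cf) || cf <= 0) {
    abort("cf must be a positive scalar", class = "fractometry_parameter_error")
  }
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) {
    abort("pad_factor must be an integer >= 1",
          class = "fractometry_parameter_error")
  }
  dc_policy <- match.arg(dc_policy, "zero")
  structure(list(cf = cf, pad_factor = pad_factor, dc_policy = dc_policy),
            class = "integration_config")
}

#' Phase-gradient components from a knife-edge set
#'
#' Opposite knife edges encode each phase-gradient component in the
#' normalised intensity difference: the x-component is
#' (Ix+ - Ix-) / (Ix+ + Ix-) up to an optical proportionality constant,
#' supplied here as `gain`. Both components are assembled into the complex
#' gradient grad_phi = gx + i * gy consumed by [integrate_phase()].
#'
#' @param ke A [knife_edge_set()].
#' @param gain Positive proportionality constant between the normalised
#'   intensity difference and the phase gradient (radians per pixel).
#' @return A list of class `gradient_field` with components `gx`, `gy`
#'   (rad/pixel) and `combined = gx + 1i * gy`.
#' @export
phase_gradients <- function(ke, gain = 1) {
  if (!inherits(ke, "knife_edge_set")) {
    abort("`ke` must be a knife_edge_set", class = "fractometry_structural_error")
  }
  if (!is.numeric(gain) || gain <= 0) {
    abort("gain must be a positive scalar", class = "fractometry_parameter_error")
  }
  sx <- ke$ix_plus + ke$ix_minus
  sy <- ke$iy_plus + ke$iy_minus
  peak <- max(sx, sy)
  if (peak <= 0) {
    abort("knife-edge set carries no intensity",
          class = "fractometry_degenerate_error")
  }
  eps <- 1e-12 * peak   # floor for dark-background denominators
  gx <- (ke$ix_plus - ke$ix_minus) / pmax(sx, eps) / gain
  gy <- (ke$iy_plus - ke$iy_minus) / pmax(sy, eps) / gain
  structure(list(gx = gx, gy = gy, combined = gx + 1i * gy),
            class = "gradient_field")
}

#' Integrate a phase-gradient field by complex Fourier integration
#'
#' The two gradient components are combined into grad_phi = gx + i * gy,
#' transformed, multiplied by the normalisation factor
#' NF = 1 / (2 * pi * (fx + i * fy)) on the frequency grid (NF = 0 at DC,
#' which fixes the additive phase gauge), inverse-transformed, and the
#' imaginary part scaled by `cf` is returned. Every periodic band-limited
#' phase is recovered exactly up to its mean; non-periodic fields should be
#' integrated with `pad_factor >= 2`.
#'
#' @param g A `gradient_field` from [phase_gradients()] (or any list with
#'   finite `gx`, `gy` matrices).
#' @param cfg An [integration_config()].
#' @return A real phase matrix (radians) with zero mean.
#' @export
integrate_phase <- function(g, cfg = integration_config()) {
  gx <- g$gx; gy <- g$gy
  stopifnot_same_shape(gx, gy)
  if (!all(is.finite(gx)) || !all(is.finite(gy))) {
    abort("gradients must be finite", class = "fractometry_structural_error")
  }
  nr <- nrow(gx); nc <- ncol(gx)
  gxp <- pad_edge(gx, cfg$pad_factor)
  gyp <- pad_edge(gy, cfg$pad_factor)
  fx <- matrix(fft_freq(ncol(gxp)), nrow(gxp), ncol(gxp), byrow = TRUE)
  fy <- matrix(fft_freq(nrow(gxp)), nrow(gxp), ncol(gxp))
  nf <- 1 / (2 * pi * (fx + 1i * fy))
  nf[1, 1] <- 0
  psi <- ifft2(nf * fft2(gxp + 1i * gyp))
  phi <- cfg$cf * Im(psi)
  phi <- crop_center(phi, nr, nc)
  phi - mean(phi)
}

#' Amplitude (bright-field) image from a knife-edge set
#'
#' The amplitude is the sum of the two opposite knife-edge images normalised
#' by the background; the x- and y-pairs must agree, and their maximum
#' relative discrepancy is recorded as a quality metric.
#'
#' @param ke A [knife_edge_set()].
#' @return A nonnegative amplitude matrix with attribute
#'   `pair_discrepancy` (max relative x-pair vs y-pair mismatch).
#' @export
amplitude_image <- function(ke) {
  if (!inherits(ke, "knife_edge_set")) {
    abort("`ke` must be a knife_edge_set", class = "fractometry_structural_error")
  }
  ax <- (ke$ix_plus + ke$ix_minus) / ke$background
  ay <- (ke$iy_plus + ke$iy_minus) / ke$background
  ref <- max(ax, 1e-300)
  structure(ax, pair_discrepancy = max(abs(ax - ay)) / ref)
}

#' Reconstruct the complex optical field from knife-edge images
#'
#' Composes [phase_gradients()], [integrate_phase()] and [amplitude_image()]
#' into a calibrated [complex_field()].
#'
#' @inheritParams phase_gradients
#' @param cfg An [integration_config()].
#' @param wavelength_um,pixel_um Acquisition metadata attached to the result.
#' @return A [complex_field()].
#' @export
reconstruct_field <- function(ke, gain = 1, cfg = integration_config(),
                              wavelength_um, pixel_um) {
  g <- phase_gradients(ke, gain)
  phi <- integrate_phase(g, cfg)
  amp <- amplitude_image(ke)
  fld <- complex_field(unclass(amp), phi, wavelength_um, pixel_um)
  attr(fld, "pair_discrepancy") <- attr(amp, "pair_discrepancy")
  fld
}

#' Complex-valued field matrix of a `complex_field`
#'
#' @param field A [complex_field()].
#' @return The complex matrix `amplitude * exp(1i * phase)`.
#' @export
field_matrix <- function(field) {
  field$amplitude * exp(1i * field$phase)
}
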