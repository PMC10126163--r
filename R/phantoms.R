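#' Weak-phase sphere phantom (microbead surrogate)
#'
#' Projection phantom of a homogeneous sphere in the anomalous-diffraction
#' regime: the phase is the chord-length projection
#' phi(x, y) = (2 * pi / lambda) * delta_n * 2 * sqrt(R^2 - rho^2) inside
#' the bead and 0 outside, with unit amplitude (weak absorption). The peak
#' phase at the centre is (2 * pi / lambda) * delta_n * 2 * R.
#'
#' @param radius_um Sphere radius (um), smaller than half the field of view.
#' @param delta_n Refractive-index contrast over the medium.
#' @param pixel_um Pixel pitch (um).
#' @param grid_size Image side length in pixels.
#' @param wavelength_um Vacuum wavelength (um).
#' @param n_medium Medium refractive index (metadata only).
#' @param center Optional sphere centre `c(x, y)` in pixels (default the
#'   grid centre).
#' @return A [complex_field()] with attribute `spec` echoing the inputs.
#' @export
sphere_phantom <- function(radius_um, delta_n, pixel_um, grid_size,
                           wavelength_um = 1.064, n_medium = 1.337,
                           center = NULL) {
  if (radius_um >= grid_size * pixel_um / 2) {
    abort("sphere must fit inside half the field of view",
          class = "fractometry_parameter_error")
  }
  if (is.null(center)) center <- rep((grid_size + 1) / 2, 2)
  x <- (seq_len(grid_size) - center[1]) * pixel_um
  y <- (seq_len(grid_size) - center[2]) * pixel_um
  rho2 <- outer(y^2, x^2, `+`)
  chord <- 2 * sqrt(pmax(radius_um^2 - rho2, 0))
  phi <- 2 * pi / wavelength_um * delta_n * chord
  fld <- complex_field(matrix(1, grid_size, grid_size), phi,
                       wavelength_um, pixel_um)
  attr(fld, "spec") <- list(radius_um = radius_um, delta_n = delta_n,
                            n_medium = n_medium, center = center)
  fld
}

#' Fractal field phantom with a prescribed power-law spectrum
#'
#' Cell-like test field whose phase has an isotropic power spectrum
#' ~ k_r^(-beta): a complex Gaussian spectrum is shaped by k_r^(-beta / 2)
#' (DC removed), inverse-transformed, rescaled to `phase_sd` radians RMS,
#' and windowed by a cosine-tapered disk envelope mimicking the cell
#' boundary. The amplitude rides on the normalised phase with a small
#' contrast. Deterministic given `seed`.
#'
#' @param beta Spectral exponent (>= 0); larger beta means smoother
#'   structure and a larger pipeline fractal dimension.
#' @param grid_size Image side length in pixels.
#' @param pixel_um Pixel pitch (um).
#' @param envelope_radius_um Envelope radius (um); default 40% of the
#'   field of view.
#' @param amplitude_contrast Amplitude modulation depth (default 0.05).
#' @param phase_sd Phase RMS contrast in radians before windowing
#'   (default 1.5, a typical quantitative-phase contrast for cells).
#' @param taper Fraction of the envelope radius over which the cosine
#'   taper falls from 1 to 0 (default 0.3).
#' @param wavelength_um Vacuum wavelength (um).
#' @param seed Integer seed recorded in the output metadata.
#' @return A [complex_field()] with attribute `spec`.
#' @export
fractal_phantom <- function(beta, grid_size, pixel_um,
                            envelope_radius_um = 0.4 * grid_size * pixel_um,
                            amplitude_contrast = 0.05, phase_sd = 1.5,
                            taper = 0.3, wavelength_um = 1.064, seed = 1L) {
  if (beta < 0) {
    abort("beta must be >= 0", class = "fractometry_parameter_error")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- grid_size
  fx <- matrix(fft_freq(n), n, n, byrow = TRUE)
  fy <- matrix(fft_freq(n), n, n)
  kr <- sqrt(fx^2 + fy^2)
  shape <- matrix(0, n, n)
  shape[kr > 0] <- kr[kr > 0]^(-beta / 2)
  spec <- (matrix(rnorm(n * n), n) + 1i * matrix(rnorm(n * n), n)) * shape
  phi <- Re(ifft2(spec))
  phi <- phi / sd(phi) * phase_sd
  # cosine-tapered disk envelope
  cxy <- (seq_len(n) - (n + 1) / 2) * pixel_um
  rho <- sqrt(outer(cxy^2, cxy^2, `+`))
  r1 <- envelope_radius_um * (1 - taper)
  w <- matrix(0, n, n)
  w[rho <= r1] <- 1
  band <- rho > r1 & rho < envelope_radius_um
  w[band] <- 0.5 * (1 + cos(pi * (rho[band] - r1) /
                              (envelope_radius_um - r1)))
  phi <- phi * w
  amp <- 1 + amplitude_contrast * phi / max(abs(phi))
  fld <- complex_field(amp, phi, wavelength_um, pixel_um)
  attr(fld, "spec") <- list(beta = beta, seed = seed,
                            envelope_radius_um = envelope_radius_um,
                            phase_sd = phase_sd,
                            amplitude_contrast = amplitude_contrast)
  fld
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Knife-edge forward model
#'
#' Simulates the four half-blocked intensity images of a complex field:
#' each opposite pair splits the local intensity B * A in two, modulated by
#' the phase-gradient component, Ix+/- = (B * A / 2) * (1 +/- gain * dphi/dx)
#' (and likewise for y), using central-difference gradients so that the
#' forward model is not the trivial inverse of the Fourier integrator.
#' Gradient terms with |gain * grad| >= 1 are clipped (with a warning) to
#' keep intensities nonnegative; optional additive Gaussian noise is
#' clipped at zero.
#'
#' @param field A [complex_field()].
#' @param background Background intensity level B (scalar or matrix).
#' @param gain Knife-edge gradient gain (radians-per-pixel scale).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Seed for the noise draw.
#' @return A [knife_edge_set()].
#' @export
knife_edge_forward <- function(field, background = 1, gain = 0.1,
                               noise_sd = 0, seed = 1L) {
  phi <- field$phase
  gx <- central_diff_x(phi)
  gy <- central_diff_y(phi)
  cap <- 1 - 1e-9
  nclip <- sum(abs(gain * gx) > cap) + sum(abs(gain * gy) > cap)
  if (nclip > 0) {
    warn(paste0("knife-edge forward model clipped ", nclip,
                " gradient value(s) with |gain * grad| >= 1"))
  }
  tx <- pmin(pmax(gain * gx, -cap), cap)
  ty <- pmin(pmax(gain * gy, -cap), cap)
  base <- background * field$amplitude / 2
  imgs <- list(
    ix_plus = base * (1 + tx), ix_minus = base * (1 - tx),
    iy_plus = base * (1 + ty), iy_minus = base * (1 - ty)
  )
  if (noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    imgs <- lapply(imgs, function(m)
      pmax(m + matrix(rnorm(length(m), sd = noise_sd), nrow(m)), 0))
  }
  bg <- if (is.matrix(background)) background else
    matrix(background, nrow(phi), ncol(phi))
  knife_edge_set(imgs$ix_plus, imgs$ix_minus, imgs$iy_plus, imgs$iy_minus, bg)
}

central_diff_x <- function(m) {
  nc <- ncol(m)
  g <- matrix(0, nrow(m), nc)
  if (nc >= 3) g[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  g[, 1] <- m[, 2] - m[, 1]
  g[, nc] <- m[, nc] - m[, nc - 1]
  g
}

central_diff_y <- function(m) {
  nr <- nrow(m)
  g <- matrix(0, nr, ncol(m))
  if (nr >= 3) g[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[nr, ] <- m[nr, ] - m[nr - 1, ]
  g
}

#' Labelled synthetic cohort of feature vectors
#'
#' Gaussian feature draws per class with prescribed per-feature mean
#' shifts and SDs — the stand-in for imaged cell cohorts when exercising
#' the profiling statistics. Deterministic given `seed`.
#'
#' @param classes A list of class specifications, each a list with `name`,
#'   `shift` (named numeric vector of per-feature means) and optional `sd`
#'   (per-feature SDs, default 1).
#' @param n_per_class Cells per class (>= 2).
#' @param seed Integer seed.
#' @return A tibble with `cell_id`, `label` and one column per feature.
#' @export
synth_cohort <- function(classes, n_per_class, seed = 1L) {
  if (length(classes) < 2 || n_per_class < 2) {
    abort("need >= 2 classes and n_per_class >= 2",
          class = "fractometry_parameter_error")
  }
  feats <- names(classes[[1]]$shift)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  rows <- purrr::map(classes, function(cl) {
    sds <- cl$sd %||% setNames(rep(1, length(feats)), feats)
    draws <- vapply(feats, function(f)
      rnorm(n_per_class, mean = cl$shift[[f]], sd = sds[[f]]),
      numeric(n_per_class))
    out <- tibble::as_tibble(matrix(draws, nrow = n_per_class,
                                    dimnames = list(NULL, feats)))
    out$label <- cl$name
    out
  })
  out <- dplyr::bind_rows(rows)
  out$cell_id <- sprintf("cell_%05d", seq_len(nrow(out)))
  out[c("cell_id", "label", feats)]
}
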