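# Mie series for a homogeneous sphere in a non-absorbing medium.
# Coefficients a_n, b_n via the logarithmic-derivative downward recurrence
# (the standard numerically stable route); angular functions pi_n, tau_n by
# upward recurrence. Truncation at N = ceil(x + 4 x^(1/3) + 2).

mie_coefficients <- function(x, m) {
  if (!is.numeric(x) || x <= 0 || x > 200) {
    abort("size parameter x must lie in (0, 200]",
          class = "fractometry_parameter_error")
  }
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  mx <- m * x
  nstart <- max(nmax, ceiling(Mod(mx))) + 15
  d <- complex(length.out = nstart + 1)  # D_n(mx), downward
  for (n in nstart:1) {
    d[n] <- (n + 1) / mx - 1 / (d[n + 1] + (n + 1) / mx)
  }
  d <- d[seq_len(nmax) + 0]  # D_1 .. D_nmax at indices 1..nmax
  # Riccati-Bessel psi_n = x j_n(x), chi_n = -x y_n(x), xi_n = psi_n - i chi_n
  psi <- numeric(nmax + 1); chi <- numeric(nmax + 1)
  psi0 <- sin(x);  psim1 <- cos(x)     # psi_0, psi_{-1}
  chi0 <- cos(x);  chim1 <- -sin(x)    # chi_0, chi_{-1}
  a <- complex(length.out = nmax); b <- complex(length.out = nmax)
  pprev <- psim1; pcur <- psi0
  cprev <- chim1; ccur <- chi0
  for (n in seq_len(nmax)) {
    pnext <- (2 * n - 1) / x * pcur - pprev
    cnext <- (2 * n - 1) / x * ccur - cprev
    psin <- pnext; chin <- cnext
    xin <- psin - 1i * chin
    xinm1 <- pcur - 1i * ccur
    da <- d[n] / m + n / x
    db <- d[n] * m + n / x
    a[n] <- (da * psin - pcur) / (da * xin - xinm1)
    b[n] <- (db * psin - pcur) / (db * xin - xinm1)
    pprev <- pcur; pcur <- pnext
    cprev <- ccur; ccur <- cnext
  }
  list(a = a, b = b, nmax = nmax)
}

#' Mie scattering amplitudes and efficiencies
#'
#' Exact series solution for plane-wave scattering by a homogeneous sphere
#' — the calibration oracle for sphere phantoms. Returns the unpolarised
#' intensity (|S1|^2 + |S2|^2) / 2 on a polar-angle grid together with the
#' extinction and scattering efficiencies.
#'
#' @param x Size parameter 2 * pi * n_medium * R / lambda, in (0, 200].
#' @param m Relative refractive index (sphere over medium).
#' @param theta Polar scattering angles in radians.
#' @return A list with `s1`, `s2` (complex amplitudes), `intensity`,
#'   `qext`, `qsca`, `nmax`.
#' @export
mie_amplitudes <- function(x, m, theta) {
  co <- mie_coefficients(x, m)
  a <- co$a; b <- co$b; nmax <- co$nmax
  mu <- cos(theta)
  s1 <- complex(length.out = length(theta))
  s2 <- complex(length.out = length(theta))
  piprev <- rep(0, length(mu))  # pi_0
  picur <- rep(1, length(mu))   # pi_1
  for (n in seq_len(nmax)) {
    taun <- n * mu * picur - (n + 1) * piprev
    fac <- (2 * n + 1) / (n * (n + 1))
    s1 <- s1 + fac * (a[n] * picur + b[n] * taun)
    s2 <- s2 + fac * (a[n] * taun + b[n] * picur)
    pinext <- ((2 * n + 1) * mu * picur - (n + 1) * piprev) / n
    piprev <- picur; picur <- pinext
  }
  nn <- seq_len(nmax)
  list(
    s1 = s1, s2 = s2,
    intensity = (Mod(s1)^2 + Mod(s2)^2) / 2,
    qext = 2 / x^2 * sum((2 * nn + 1) * Re(a + b)),
    qsca = 2 / x^2 * sum((2 * nn + 1) * (Mod(a)^2 + Mod(b)^2)),
    nmax = nmax
  )
}

#' Analytical Mie ALS profile for a sphere specification
#'
#' Evaluates the Mie series for a homogeneous sphere matching a phantom
#' specification and maps the polar angle to the scattering wave vector
#' q = (4 * pi / lambda) * sin(theta / 2), yielding a reference ALS
#' profile against which phantom FTLS output can be validated (minima
#' positions in particular).
#'
#' @param radius_um Sphere radius (um).
#' @param delta_n Refractive-index contrast over the medium.
#' @param n_medium Medium refractive index.
#' @param wavelength_um Vacuum wavelength (um).
#' @param theta Polar angle grid (radians), default 0 to 0.5 rad.
#' @return An `als_profile` tibble (`q`, `theta`, `s`, `counts = 1`).
#' @export
mie_als <- function(radius_um, delta_n, n_medium = 1.337,
                    wavelength_um = 1.064,
                    theta = seq(0, 0.5, length.out = 512)) {
  x <- 2 * pi * n_medium * radius_um / wavelength_um
  m <- (n_medium + delta_n) / n_medium
  amp <- mie_amplitudes(x, m, theta)
  out <- tibble::tibble(
    q = 4 * pi / wavelength_um * sin(theta / 2),
    theta = theta,
    s = amp$intensity,
    counts = 1L
  )
  structure(out, class = c("als_profile", class(out)),
            wavelength_um = wavelength_um,
            bin_width = if (length(theta) > 1) diff(out$q[1:2]) else NA_real_,
            size_parameter = x, nmax = amp$nmax)
}
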