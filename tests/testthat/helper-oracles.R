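# Independent oracles and fixture builders. Everything here is deliberately
# naive (enumeration, direct summation, textbook Bessel identities) so the
# package's fast paths are checked against a second, unrelated route.

# Periodic circular shift of a matrix by (dy, dx) pixels.
circ_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1,
    drop = FALSE]
}

# Brute-force periodic spatial autocorrelation R(dy, dx) = sum E conj(E_shift),
# evaluated on lags |dy|, |dx| <= max_lag (NULL: all lags). Returns a data
# frame of signed lags and |R|.
brute_autocorr <- function(e, max_lag = NULL) {
  nr <- nrow(e); nc <- ncol(e)
  dys <- if (is.null(max_lag)) 0:(nr - 1) else
    ((-max_lag):max_lag) %% nr
  dxs <- if (is.null(max_lag)) 0:(nc - 1) else
    ((-max_lag):max_lag) %% nc
  dys <- unique(dys); dxs <- unique(dxs)
  out <- expand.grid(dy = dys, dx = dxs)
  out$mod <- mapply(function(dy, dx) {
    Mod(sum(e * Conj(circ_shift(e, dy, dx))))
  }, out$dy, out$dx)
  # signed lags as used by the package's frequency bookkeeping
  out$sdy <- ifelse(out$dy >= ceiling(nr / 2), out$dy - nr, out$dy)
  out$sdx <- ifelse(out$dx >= ceiling(nc / 2), out$dx - nc, out$dx)
  out
}

# Radially averaged, zero-lag-normalised correlation curve from the brute
# autocorrelation, mirroring the package binning (one-pixel bins).
brute_correlation_curve <- function(e, pixel_um, max_lag = NULL) {
  ac <- brute_autocorr(e, max_lag)
  r <- pixel_um * sqrt(ac$sdy^2 + ac$sdx^2)
  c0 <- ac$mod[ac$dy == 0 & ac$dx == 0]
  bin <- floor(r / pixel_um + 0.5)
  cc <- tapply(ac$mod / c0, bin, mean)
  rr <- as.integer(names(cc)) * pixel_um
  keep <- rr >= pixel_um
  data.frame(r = rr[keep], c = as.numeric(cc[keep]))
}

# Log-log OLS fractal fit, written independently of the package.
brute_fd_fit <- function(r, c, r_lo, r_hi) {
  keep <- r >= r_lo & r <= r_hi & c > 0
  x <- log10(r[keep]); y <- log10(c[keep])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  3 + slope
}

# Mie efficiencies via half-integer Bessel functions (Bohren-Huffman
# formulas evaluated with base besselJ/besselY — a second implementation
# independent of the logarithmic-derivative recurrence).
bessel_mie_qext <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  psi <- function(n, z) sqrt(pi * z / 2) * besselJ(z, n + 0.5)
  chi <- function(n, z) -sqrt(pi * z / 2) * besselY(z, n + 0.5)
  xi <- function(n, z) psi(n, z) - 1i * chi(n, z)
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  n <- seq_len(nmax)
  a <- (m * psi(n, m * x) * dpsi(n, x) - psi(n, x) * dpsi(n, m * x)) /
       (m * psi(n, m * x) * dxi(n, x) - xi(n, x) * dpsi(n, m * x))
  b <- (psi(n, m * x) * dpsi(n, x) - m * psi(n, x) * dpsi(n, m * x)) /
       (psi(n, m * x) * dxi(n, x) - m * xi(n, x) * dpsi(n, m * x))
  2 / x^2 * sum((2 * n + 1) * Re(a + b))
}

# Cliff's delta by full pair enumeration.
enum_cliffs <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) {
    gt <- gt + sum(xi > y)
    lt <- lt + sum(xi < y)
  }
  (gt - lt) / (length(x) * length(y))
}

# Injected correlation curve from (r, c) values.
synthetic_curve <- function(r, c) {
  structure(tibble::tibble(r = r, c = c, log_r = log10(r), log_c = log10(c)),
            class = c("correlation_curve", "tbl_df", "tbl", "data.frame"),
            pixel_um = min(r))
}

# Piecewise log-log curve: flat until l1, slope `slope` on [l1, l2], flat after.
piecewise_curve <- function(l_lo = -1, l_hi = 1, n = 61,
                            l1 = -0.3, l2 = 0.5, slope = -1) {
  lr <- seq(l_lo, l_hi, length.out = n)
  lc <- ifelse(lr < l1, 0,
        ifelse(lr <= l2, slope * (lr - l1), slope * (l2 - l1)))
  synthetic_curve(10^lr, 10^lc)
}

# Smooth Gaussian-bump phase field for round-trip checks.
gaussian_bump_field <- function(n = 64, sigma_px = 8, peak = 1.2,
                                wavelength_um = 1.064, pixel_um = 0.2) {
  cx <- seq_len(n) - (n + 1) / 2
  phi <- peak * exp(-outer(cx^2, cx^2, `+`) / (2 * sigma_px^2))
  complex_field(matrix(1, n, n), phi, wavelength_um, pixel_um)
}

# Analytic gradients of a single periodic Fourier mode along x.
fourier_mode_gradients <- function(n = 64, cycles = 1) {
  xi <- matrix(rep(0:(n - 1), each = n), n)  # column (x) index
  phi <- sin(2 * pi * cycles * xi / n)
  list(phi = phi,
       gx = 2 * pi * cycles / n * cos(2 * pi * cycles * xi / n),
       gy = matrix(0, n, n))
}

# Periodic 90-degree rotation on the sampling torus.
rot90_periodic <- function(m) {
  n <- nrow(m)
  out <- matrix(m[1], n, n)
  for (r in 0:(n - 1)) {
    out[r + 1, ] <- m[((0:(n - 1))) + 1, ((n - r) %% n) + 1]
  }
  out
}
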