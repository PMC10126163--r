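# Fourier bookkeeping shared by the field-integration and scattering code.
# Convention (used everywhere): images are row-major matrices with x = columns,
# y = rows, origin at the top-left; frequency grids are centred after fftshift
# (DC at element [n %/% 2 + 1]).

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Unshifted FFT sample frequencies in cycles per sample (numpy fftfreq order).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  hi <- k >= ceiling(n / 2)
  k[hi] <- k[hi] - n
  k / n
}

# Move DC from [1,1] to the centre of the matrix (and back).
fftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((nr %/% 2 + 1):nr, 1:(nr %/% 2)), c((nc %/% 2 + 1):nc, 1:(nc %/% 2))]
}

ifftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- nr - nr %/% 2; sc <- nc - nc %/% 2
  m[c((sr + 1):nr, 1:sr), c((sc + 1):nc, 1:sc)]
}

# Replicate-edge padding to (pad_factor * n) with the original block centred.
pad_edge <- function(m, pad_factor) {
  if (pad_factor <= 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- nr * pad_factor; nc2 <- nc * pad_factor
  r0 <- (nr2 - nr) %/% 2
  c0 <- (nc2 - nc) %/% 2
  ridx <- pmin(pmax(seq_len(nr2) - r0, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc2) - c0, 1L), nc)
  m[ridx, cidx, drop = FALSE]
}

crop_center <- function(m, nr, nc) {
  r0 <- (nrow(m) - nr) %/% 2
  c0 <- (ncol(m) - nc) %/% 2
  m[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

pad_zero <- function(m, pad_factor) {
  if (pad_factor <= 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0 + 0i, nr * pad_factor, nc * pad_factor)
  r0 <- (nrow(out) - nr) %/% 2
  c0 <- (ncol(out) - nc) %/% 2
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- m
  out
}

# Ring average of `values` over `radius`, fixed bin width; empty bins dropped.
radial_average <- function(radius, values, bin_width) {
  bin <- as.integer(floor(radius / bin_width + 0.5))
  s <- tapply(values, bin, mean)
  n <- tapply(values, bin, length)
  idx <- as.integer(names(s))
  tibble::tibble(
    bin = idx,
    radius = idx * bin_width,
    mean = as.numeric(s),
    counts = as.integer(n)
  )
}

stopifnot_same_shape <- function(...) {
  mats <- list(...)
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d)) {
      abort("all images in a knife-edge set must share one shape",
            class = "fractometry_structural_error")
    }
  }
  invisible(d)
}
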