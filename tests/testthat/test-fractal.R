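test_that("injected power laws return FD = 3 - alpha with zero MSE", {
  r <- 10^seq(-1, 1, length.out = 40)
  for (alpha in c(0, 0.5, 1.5, 2.3, 3)) {
    for (k in c(1, 0.01, 50)) {
      fit <- fit_overall_fd(synthetic_curve(r, k * r^(-alpha)), 0.1, 10)
      expect_equal(fit$fd, 3 - alpha, tolerance = 1e-12)
      expect_lt(fit$mse, 1e-24)
      expect_equal(fit$fd, 3 - fit$alpha)  # identity holds exactly
    }
  }
})

test_that("a flat curve fits FD = 3 and too-few bins error out", {
  r <- 10^seq(-1, 1, length.out = 20)
  fit <- fit_overall_fd(synthetic_curve(r, rep(2, 20)), 0.1, 10)
  expect_equal(fit$fd, 3, tolerance = 1e-12)
  expect_equal(fit$mse, 0, tolerance = 1e-24)
  expect_error(fit_overall_fd(synthetic_curve(r, r^-1), 0.1, 0.13),
               class = "fractometry_insufficient_data_error")
})

test_that("alternating +/-0.1 log residuals give MSE exactly 0.01", {
  # duplicated abscissae make the +/- pattern orthogonal to the design,
  # so OLS returns the injected residuals verbatim
  lr <- rep(seq(-1, 1, length.out = 10), each = 2)
  eps <- rep(c(0.1, -0.1), 10)
  curve <- synthetic_curve(10^lr, 10^(-0.5 * lr + eps))
  fit <- fit_overall_fd(curve, 0.05, 20)
  expect_equal(fit$mse, 0.01, tolerance = 1e-12)
  expect_equal(fit$fd, 2.5, tolerance = 1e-12)
})

test_that("a pure power law yields a full-range fractal window", {
  r <- 10^seq(-1, 1, length.out = 41)
  curve <- synthetic_curve(r, r^-0.8)
  overall <- fit_overall_fd(curve, min(r), max(r))
  fw <- detect_fractal_window(curve, overall)
  expect_false(fw$fallback)
  # local slopes are only defined where the regression window fits
  expect_lte(fw$r_min, r[3] * (1 + 1e-9))
  expect_gte(fw$r_max, r[39] * (1 - 1e-9))
})

test_that("the window of a piecewise curve matches the break points", {
  curve <- piecewise_curve(l1 = -0.3, l2 = 0.5)
  overall <- fit_overall_fd(curve, min(curve$r), max(curve$r))
  fw <- detect_fractal_window(curve, overall)
  bin <- diff(log10(curve$r[1:2]))
  expect_false(fw$fallback)
  expect_lt(abs(log10(fw$r_min) - (-0.3)), bin * 1.5)
  expect_lt(abs(log10(fw$r_max) - 0.5), bin * 1.5)
  inwin <- fit_fd_within_window(curve, fw)
  expect_equal(inwin$fd, 2.0, tolerance = 0.02)
})

test_that("of two equally steep runs the longer one is selected", {
  # slope -1 on [-0.9, -0.5] (0.4 decades) and on [0.1, 0.9] (0.8 decades)
  lr <- seq(-1, 1, length.out = 81)
  seg <- function(l) {
    if (l < -0.9) 0
    else if (l <= -0.5) -(l + 0.9)
    else if (l < 0.1) -0.4
    else if (l <= 0.9) -0.4 - (l - 0.1)
    else -1.2
  }
  curve <- synthetic_curve(10^lr, 10^vapply(lr, seg, numeric(1)))
  overall <- fit_overall_fd(curve, min(curve$r), max(curve$r))
  fw <- detect_fractal_window(curve, overall)
  expect_gt(log10(fw$r_min), -0.1)   # the long run starts near 0.1
  expect_gt(fw$width_decades, 0.6)
})

test_that("window detection falls back to the whole range when nothing qualifies", {
  r <- 10^seq(-1, 1, length.out = 15)
  set.seed(5)
  curve <- synthetic_curve(r, 10^rnorm(15, 0, 0.001))
  overall <- fit_overall_fd(curve, min(r), max(r))
  fw <- detect_fractal_window(curve, overall, min_bins = 14L,
                              min_decades = 1.9)
  expect_true(fw$fallback)
  expect_equal(fw$r_min, overall$r_lo)
  expect_equal(fw$r_max, overall$r_hi)
  expect_equal(fit_fd_within_window(curve, fw)$fd, overall$fd)
})

test_that("feature extraction is scale equivariant", {
  curve <- piecewise_curve()
  overall <- fit_overall_fd(curve, min(curve$r), max(curve$r))
  fw <- detect_fractal_window(curve, overall)
  # multiplying c by a constant changes neither FD nor the window
  curve2 <- synthetic_curve(curve$r, 7.3 * curve$c)
  overall2 <- fit_overall_fd(curve2, min(curve2$r), max(curve2$r))
  fw2 <- detect_fractal_window(curve2, overall2)
  expect_equal(overall2$fd, overall$fd, tolerance = 1e-12)
  expect_equal(c(fw2$r_min, fw2$r_max, fw2$width_decades),
               c(fw$r_min, fw$r_max, fw$width_decades), tolerance = 1e-12)
  # rescaling r by gamma shifts the window but not FD or its width
  gam <- 4
  curve3 <- synthetic_curve(gam * curve$r, curve$c)
  overall3 <- fit_overall_fd(curve3, gam * min(curve$r), gam * max(curve$r))
  fw3 <- detect_fractal_window(curve3, overall3)
  expect_equal(overall3$fd, overall$fd, tolerance = 1e-12)
  expect_equal(fw3$r_min, gam * fw$r_min, tolerance = 1e-9)
  expect_equal(fw3$r_max, gam * fw$r_max, tolerance = 1e-9)
  expect_equal(fw3$width_decades, fw$width_decades, tolerance = 1e-9)
})

test_that("ALS statistics behave on constant and power-law profiles", {
  make_als <- function(q, s) {
    structure(tibble::tibble(q = q, theta = q, s = s, counts = 1L),
              class = c("als_profile", "tbl_df", "tbl", "data.frame"),
              wavelength_um = 1.064, bin_width = diff(q[1:2]))
  }
  q <- 10^seq(-1, 1, length.out = 32)
  st <- als_statistics(make_als(q, rep(4, 32)))
  expect_equal(st$als_log_sd, 0)
  expect_equal(st$als_log_skew, 0)
  expect_equal(st$als_log_kurt, 0)
  expect_equal(st$als_slope, 0, tolerance = 1e-12)
  st2 <- als_statistics(make_als(q, q^-2))
  expect_equal(st2$als_slope, -2, tolerance = 1e-9)
  # band fractions partition the energy
  expect_equal(st2$als_frac_lowq + st2$als_frac_midq + st2$als_frac_highq, 1,
               tolerance = 1e-12)
  expect_error(als_statistics(make_als(q[1:5], rep(1, 5))),
               class = "fractometry_insufficient_data_error")
})

test_that("fractal_profile emits the 17-feature catalog in fixed order", {
  f <- fractal_phantom(beta = 2, grid_size = 48, pixel_um = 0.2, seed = 9)
  prof <- fractal_profile(f, cell_id = "c1")
  expect_identical(names(prof), c("cell_id", fractal_feature_names()))
  expect_true(all(vapply(prof[fractal_feature_names()], is.finite,
                         logical(1))))
  expect_equal(prof$fd_width, abs(prof$fd - prof$fd_with_fw))
  # a uniform field degenerates to FD = 3
  u <- complex_field(matrix(1, 48, 48), matrix(0, 48, 48), 1.064, 0.2)
  up <- fractal_profile(u)
  expect_equal(up$fd, 3, tolerance = 1e-9)
  expect_true(attr(up, "degenerate"))
  expect_identical(ncol(up), 17L)
})

test_that("pipeline FD is strictly monotone in the spectral exponent", {
  # smoother phase fields (larger beta) decorrelate over visible scales, so
  # the correlation curve steepens and FD falls away from the white-field
  # limit of 3
  fds <- vapply(c(1, 2, 3), function(beta) {
    mean(vapply(1:3, function(s) {
      f <- fractal_phantom(beta = beta, grid_size = 64, pixel_um = 0.2,
                           seed = 100 + s)
      fractal_profile(f)$fd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fds) < 0))
  expect_lt(max(fds), 3)
})
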