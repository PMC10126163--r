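test_that("the sphere phantom has the analytic peak phase and OPL volume", {
  lam <- 1.064; pix <- 0.1; r_um <- 2; dn <- 0.015
  # integer-pixel centre so the peak-phase formula is sampled exactly
  f <- sphere_phantom(radius_um = r_um, delta_n = dn, pixel_um = pix,
                      grid_size = 64, center = c(32, 32))
  expect_equal(max(f$phase), 2 * pi / lam * dn * 2 * r_um, tolerance = 1e-9)
  expect_equal(f$amplitude, matrix(1, 64, 64))
  # integrated OPL equals sphere volume times delta_n (>= 8 px per radius)
  opl_sum <- sum(f$phase) * lam / (2 * pi) * pix^2
  expect_equal(opl_sum, 4 / 3 * pi * r_um^3 * dn, tolerance = 0.005)
  expect_error(sphere_phantom(10, 0.01, 0.1, 64),
               class = "fractometry_parameter_error")
  # delta_n = 0 gives a uniform field
  f0 <- sphere_phantom(1, 0, 0.1, 32)
  expect_equal(max(abs(f0$phase)), 0)
})

test_that("Mie series matches the Rayleigh limit and an independent Bessel route", {
  th <- seq(0, pi, length.out = 181)
  amp <- mie_amplitudes(0.05, 1.1, th)
  ray <- 1 + cos(th)^2
  expect_lt(max(abs(amp$intensity / amp$intensity[1] - ray / ray[1])), 0.01)
  for (case in list(c(10, 1.5), c(5, 1.33), c(0.5, 1.2))) {
    expect_equal(mie_amplitudes(case[1], case[2], 0)$qext,
                 bessel_mie_qext(case[1], case[2]), tolerance = 1e-6)
  }
  # forward lobe dominates
  expect_equal(which.max(mie_amplitudes(10, 1.2, th)$intensity), 1L)
  expect_error(mie_amplitudes(500, 1.2, 0),
               class = "fractometry_parameter_error")
})

test_that("mie_als maps angles to wave vectors consistently", {
  als <- mie_als(radius_um = 3, delta_n = 0.06, n_medium = 1.337,
                 wavelength_um = 1.064)
  expect_equal(als$q, 4 * pi / 1.064 * sin(als$theta / 2), tolerance = 1e-12)
  expect_true(all(als$s >= 0))
  expect_gt(attr(als, "size_parameter"), 0)
})

test_that("the phantom first ALS minimum sits within one q-bin of the Airy prediction", {
  n <- 64; pix <- 0.2; lam <- 1.064; r_um <- 2.4  # R = 12 px
  f <- sphere_phantom(radius_um = r_um, delta_n = 0.002, pixel_um = pix,
                      grid_size = n, wavelength_um = lam)
  als <- angular_profile(far_field_pattern(f))
  s <- als$s[als$q > 0]; q <- als$q[als$q > 0]
  first_min <- q[which(diff(sign(diff(s))) > 0)[1] + 1]
  q_airy <- 2 * pi / lam * 0.61 * lam / r_um
  expect_lt(abs(first_min - q_airy), attr(als, "bin_width"))
})

test_that("fractal phantoms are seed-deterministic and beta = 0 decorrelates", {
  f1 <- fractal_phantom(beta = 1.5, grid_size = 32, pixel_um = 0.2, seed = 42)
  f2 <- fractal_phantom(beta = 1.5, grid_size = 32, pixel_um = 0.2, seed = 42)
  expect_identical(f1$phase, f2$phase)
  expect_identical(f1$amplitude, f2$amplitude)
  f3 <- fractal_phantom(beta = 1.5, grid_size = 32, pixel_um = 0.2, seed = 43)
  expect_gt(max(abs(f1$phase - f3$phase)), 0)
  # white phantom: correlation at 2 px already near the floor (same-realization
  # brute-force oracle agrees)
  w <- fractal_phantom(beta = 0, grid_size = 32, pixel_um = 0.2, seed = 4,
                       phase_sd = 3)
  curve <- density_correlation(far_field_pattern(w))
  oracle <- brute_correlation_curve(field_matrix(w), 0.2)
  joined <- merge(as.data.frame(curve)[c("r", "c")], oracle, by = "r")
  expect_lt(max(abs(joined$c.x - joined$c.y) / joined$c.y), 1e-6)
  # normalised correlation collapses from 1 at zero lag to the envelope
  # plateau within the first retained bin
  expect_lt(curve$c[1], 0.75)
})

test_that("the knife-edge forward model keeps both pair sums equal to B*A", {
  f <- gaussian_bump_field(48)
  ke <- knife_edge_forward(f, background = 1.3, gain = 0.1)
  ba <- 1.3 * f$amplitude
  expect_equal(ke$ix_plus + ke$ix_minus, ba, tolerance = 1e-12)
  expect_equal(ke$iy_plus + ke$iy_minus, ba, tolerance = 1e-12)
  # steep phases are clipped with a warning
  steep <- complex_field(matrix(1, 16, 16),
                         matrix(seq(0, 60, length.out = 256), 16), 1.064, 0.2)
  expect_warning(knife_edge_forward(steep, gain = 1), "clipped")
})

test_that("noise degrades the knife-edge round trip monotonically", {
  f <- gaussian_bump_field(64)
  rmse <- vapply(c(0, 0.002, 0.02), function(ns) {
    ke <- knife_edge_forward(f, gain = 0.1, noise_sd = ns, seed = 8)
    fr <- reconstruct_field(ke, gain = 0.1,
                            cfg = integration_config(pad_factor = 2),
                            wavelength_um = 1.064, pixel_um = 0.2)
    phi <- fr$phase - mean(fr$phase) + mean(f$phase)
    sqrt(mean((phi - f$phase)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
  expect_lt(rmse[1] / sd(f$phase), 0.01)
})

test_that("synthetic cohorts are reproducible and carry the requested shifts", {
  classes <- list(
    list(name = "ctrl", shift = c(fd = 0, mse = 0)),
    list(name = "drug", shift = c(fd = 1, mse = 0.5))
  )
  c1 <- synth_cohort(classes, n_per_class = 200, seed = 3)
  c2 <- synth_cohort(classes, n_per_class = 200, seed = 3)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 400L)
  expect_equal(mean(c1$fd[c1$label == "drug"]) - mean(c1$fd[c1$label == "ctrl"]),
               1, tolerance = 0.25)
  expect_error(synth_cohort(classes[1], 10),
               class = "fractometry_parameter_error")
})
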