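test_that("z-scoring standardises, drops dead features, and is idempotent", {
  set.seed(1)
  d <- tibble::tibble(cell_id = sprintf("c%02d", 1:50), label = "a",
                      f1 = rnorm(50, 5, 2), f2 = runif(50), f3 = 1)
  expect_warning(z <- zscore_features(d), "zero-variance")
  expect_false("f3" %in% names(z))
  expect_equal(mean(z$f1), 0, tolerance = 1e-12)
  expect_equal(sd(z$f2), 1, tolerance = 1e-12)
  z2 <- zscore_features(z)
  expect_equal(z2$f1, z$f1, tolerance = 1e-12)
})

test_that("Cliff's delta matches pair enumeration, including ties", {
  expect_equal(cliffs_delta(c(1, 2), c(2, 3)), -0.75)
  expect_equal(cliffs_delta(1:5, 1:5), 0)
  expect_equal(cliffs_delta(6:10, 1:5), 1)
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- sample(3:10, 25, replace = TRUE)
    expect_equal(cliffs_delta(x, y), enum_cliffs(x, y), tolerance = 1e-12)
  }
  expect_error(cliffs_delta(numeric(0), 1),
               class = "fractometry_parameter_error")
})

test_that("AUROC equals (Cliff's delta + 1)/2 and handles ties at 0.5", {
  set.seed(9)
  for (i in 1:20) {
    s <- c(rnorm(40), rnorm(30, 0.5))
    l <- c(rep(FALSE, 40), rep(TRUE, 30))
    a <- auroc(s, l)$auroc
    expect_equal(a, (cliffs_delta(s[l], s[!l]) + 1) / 2, tolerance = 1e-12)
  }
  expect_equal(auroc(rep(1, 20), rep(c(TRUE, FALSE), 10))$auroc, 0.5)
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auroc, 1)
})

test_that("the ROC curve is a valid trapezoid-consistent sweep", {
  set.seed(3)
  s <- c(rnorm(50), rnorm(50, 1)); l <- rep(c(FALSE, TRUE), each = 50)
  s[1:10] <- s[11:20]  # inject ties
  roc <- auroc(s, l)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(range(roc$tpr), c(0, 1))
  expect_equal(range(roc$fpr), c(0, 1))
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, roc$auroc, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(roc$auroc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the linear one-vs-all classifier separates, and duplicated features change nothing", {
  set.seed(21)
  d <- tibble::tibble(label = rep(c("a", "b"), each = 30),
                      f1 = c(rnorm(30, 0), rnorm(30, 8)),
                      f2 = rnorm(60))
  fit <- linear_ova_classifier(d, positive = "a")
  expect_equal(fit$roc$auroc, 1)
  d2 <- d; d2$f1_copy <- d$f1
  fit2 <- linear_ova_classifier(d2, positive = "a")
  expect_equal(fit2$scores, fit$scores, tolerance = 1e-8)
  expect_error(linear_ova_classifier(dplyr::filter(d, label == "a"), "a"),
               class = "fractometry_parameter_error")
})

test_that("Spearman correlation respects monotone transforms and independence", {
  set.seed(5)
  d <- tibble::tibble(f1 = rnorm(200))
  d$f2 <- exp(d$f1)        # monotone transform
  d$f3 <- -d$f1            # sign flip
  m <- spearman_matrix(d)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["f1", "f2"], 1)
  expect_equal(m["f1", "f3"], -1)
  big <- tibble::tibble(u1 = runif(5000), u2 = runif(5000))
  expect_lt(abs(spearman_matrix(big)["u1", "u2"]), 0.05)
  edges <- correlation_edges(m, 0.6)
  expect_true(all(abs(edges$rho) > 0.6))
  expect_true(all(c("f1", "f2") %in% c(edges$feature_a, edges$feature_b)))
})

test_that("feature ranking screens one-vs-all discrimination", {
  set.seed(13)
  d <- tibble::tibble(
    label = rep(c("a", "b", "c"), each = 40),
    ordered = c(rnorm(40, 0, 0.1), rnorm(40, 5, 0.1), rnorm(40, 10, 0.1)),
    flat = rep(1, 120),
    noise = rnorm(120)
  )
  rk <- rank_features(d)
  expect_setequal(rk$feature, c("ordered", "flat", "noise"))
  expect_identical(rk$feature[1], "ordered")
  # a feature identical across classes scores exactly 0.5 per class
  expect_equal(rk$mean_auroc[rk$feature == "flat"], 0.5)
  # the perfectly ordering feature separates the two outer classes fully
  expect_equal(rk$auroc_a[rk$feature == "ordered"], 1)
  expect_equal(rk$auroc_c[rk$feature == "ordered"], 1)
})

test_that("profiling statistics are invariant to row permutation", {
  set.seed(17)
  d <- tibble::tibble(label = rep(c("a", "b"), each = 25),
                      f1 = rnorm(50), f2 = rnorm(50))
  perm <- sample(50)
  dp <- d[perm, ]
  expect_equal(linear_ova_classifier(dp, "a")$roc$auroc,
               linear_ova_classifier(d, "a")$roc$auroc, tolerance = 1e-12)
  expect_equal(spearman_matrix(dp), spearman_matrix(d), tolerance = 1e-12)
  expect_equal(rank_features(dp)$mean_auroc, rank_features(d)$mean_auroc,
               tolerance = 1e-12)
})

test_that("tidiers return the expected shapes", {
  r <- 10^seq(-1, 1, length.out = 20)
  fit <- fit_overall_fd(synthetic_curve(r, r^-0.5), 0.1, 10)
  expect_identical(tidy(fit)$term, c("intercept", "slope", "alpha", "fd"))
  expect_equal(glance(fit)$fd, 2.5, tolerance = 1e-12)
  roc <- auroc(c(1, 2, 3, 4), c(F, F, T, T))
  expect_identical(names(tidy(roc)), c("threshold", "fpr", "tpr"))
  expect_equal(glance(roc)$auroc, 1)
})
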