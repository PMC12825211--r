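make_series <- function(x, y, lik, fps = 60) {
  K <- ncol(as.matrix(x))
  keypoint_series(x, y, lik, bodyparts = hindlimb_keypoints()[seq_len(K)],
                  fps = fps)
}

test_that("likelihood filter masks strictly below threshold", {
  lik <- matrix(c(0.9, 0.4, 0.6), 3, 1)
  s <- make_series(matrix(1:3, 3, 1), matrix(4:6, 3, 1), lik)
  f <- filter_low_likelihood(s, 0.5)
  expect_equal(is.na(f$x[, 1]), c(FALSE, TRUE, FALSE))
  expect_equal(attr(f, "n_masked"), 1L)

  expect_equal(attr(filter_low_likelihood(s, 0), "n_masked"), 0L)
  # threshold 1 masks every cell below likelihood 1 (and warns: hip empty)
  expect_warning(f1 <- filter_low_likelihood(s, 1), "hip")
  expect_equal(attr(f1, "n_masked"), 3L)
  expect_warning(filter_low_likelihood(
    make_series(matrix(1, 3, 1), matrix(1, 3, 1), matrix(0.1, 3, 1)), 0.5),
    "hip")
})

test_that("median imputation fills masked cells with the keypoint median", {
  x <- matrix(c(1, NA, 3, 5), 4, 1)
  s <- make_series(x, x, matrix(1, 4, 1))
  s$x[2, 1] <- NA; s$y[2, 1] <- NA
  imp <- impute_median(s)
  expect_equal(unname(imp$x[2, 1]), 3)  # median(1, 3, 5)

  # no masked cells: identity
  s2 <- make_series(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2),
                    matrix(1, 4, 2))
  expect_equal(impute_median(s2), s2)

  # all but one masked: every masked cell takes the single observed value
  s3 <- make_series(matrix(c(NA, 7, NA, NA), 4, 1),
                    matrix(c(NA, 2, NA, NA), 4, 1), matrix(1, 4, 1))
  imp3 <- impute_median(s3)
  expect_true(all(imp3$x == 7) && all(imp3$y == 2))

  s4 <- make_series(matrix(NA_real_, 4, 1), matrix(NA_real_, 4, 1),
                    matrix(1, 4, 1))
  expect_error(impute_median(s4), "fully masked")
})

test_that("Euclidean flattening matches the distance formula", {
  s <- make_series(matrix(3, 2, 1), matrix(4, 2, 1), matrix(1, 2, 1))
  expect_equal(unname(flatten_euclidean(s)[, 1]), c(5, 5))  # 3-4-5
  s0 <- make_series(matrix(0, 2, 1), matrix(0, 2, 1), matrix(1, 2, 1))
  expect_equal(unname(flatten_euclidean(s0)[, 1]), c(0, 0))
  # hip-anchored: the hip column itself is identically zero
  trial <- tiny_trial()
  ha <- flatten_euclidean(trial$series, origin = "hip_anchored")
  expect_true(all(ha[, "hip"] == 0))
})

test_that("standardization uses the population convention and inverts exactly", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "hip"))
  z <- standardize(m)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)  # population SD
  expect_equal(unstandardize(z), m, tolerance = 1e-9)
  expect_error(standardize(cbind(m, knee = c(2, 2, 2))), "knee")

  # invariance to positive column-wise affine rescaling
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(unclass(standardize(x * 3 + 10)), unclass(standardize(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # idempotence on standardized input
  expect_equal(unclass(standardize(unclass(standardize(x)))),
               unclass(standardize(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("movement gate retains moving configurations and drops static ones", {
  # static trial: no movement anywhere, nothing retained
  epochs <- epoch_table(data.frame(
    label = c(1L, 2L), mode = "BP2",
    on_start = c(0L, 600L), on_end = c(300L, 900L),
    off_start = c(300L, 900L), off_end = c(600L, 1200L),
    subject_id = "S1"))
  static <- matrix(5, 1200, 10)
  gated <- movement_gate(static, epochs, fps = 60)
  expect_false(any(gated$retained))

  # synthetic trial where exactly one configuration moves
  lib <- motif_library(c(1L, 2L), "selective", seed = 2)
  lib$motifs[[2]]$drive <- rep(0, 3)        # config 2: no attractor pull
  lib$motifs[[2]]$noise_sd <- 0
  spec <- trial_spec(n_configs = 2, noise_px = 0.5, dropout_rate = 0,
                     seed = 3)
  trial <- generate_trial(spec, lib, labels = c(1L, 2L))
  vals <- flatten_euclidean(trial$series)
  g <- movement_gate(vals, trial$epochs, fps = 60)
  expect_equal(g$retained, c(TRUE, FALSE))

  # k_sd = 0 with noise: every configuration clears the baseline mean
  g0 <- movement_gate(vals, trial$epochs, fps = 60, k_sd = 0)
  expect_true(all(g0$retained))

  no_off <- transform(as.data.frame(epochs),
                      off_start = on_end, off_end = on_end)
  expect_error(movement_gate(static, no_off, fps = 60), "no OFF frames")
})

test_that("tracking error reports per-keypoint and pooled medians in mm", {
  trial <- tiny_trial()
  s <- trial$series
  expect_equal(evaluate_tracking_error(s, s, 0.5)$overall_mm, 0)

  shifted <- s
  shifted$x <- s$x + 1   # constant 1 px offset in x
  err <- evaluate_tracking_error(shifted, s, mm_per_px = 0.5)
  expect_equal(unname(err$per_keypoint_mm), rep(0.5, 10))
  expect_equal(err$overall_mm, 0.5)

  # direct median oracle on a hand-built error sequence
  a <- make_series(matrix(c(0.1, 0.3, 0.9), 3, 1), matrix(0, 3, 1),
                   matrix(1, 3, 1))
  b <- make_series(matrix(0, 3, 1), matrix(0, 3, 1), matrix(1, 3, 1))
  expect_equal(unname(evaluate_tracking_error(a, b, 1)$per_keypoint_mm),
               0.3)

  bad <- s; bad$bodyparts <- rev(bad$bodyparts)
  expect_error(evaluate_tracking_error(bad, s, 1), "mismatch")
})

test_that("high-amplitude regimes pass the gate and preprocessing is complete", {
  prep <- selective_trial()$prep
  expect_true(all(prep$epochs$retained))
  expect_false(anyNA(prep$values))
  expect_equal(unname(colMeans(prep$values)), rep(0, 10), tolerance = 1e-6)
  expect_equal(unname(apply(prep$values, 2, function(c) sqrt(mean(c^2)))),
               rep(1, 10), tolerance = 1e-6)
})
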