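# Fixtures: switching vector autoregressions with known parameters.

two_state_fixture <- function() cached("arhmm_two_state", function() {
  A <- list(0.9 * rot3(c(0, 0, 1), 0.25), 0.9 * rot3(c(1, 0, 0), 0.6))
  dr <- list(as.numeric((diag(3) - A[[1]]) %*% c(2, 0, 0)),
             as.numeric((diag(3) - A[[2]]) %*% c(-2, 1, 0)))
  c(make_switching_var(1500, A, dr, dwell = 60, noise_sd = 0.1, seed = 5),
    list(A = A, drive = dr))
})

test_that("single-state AR parameters are recovered from VAR data", {
  A <- 0.92 * rot3(c(0.3, 1, 0.2), 0.4)
  dr <- as.numeric((diag(3) - A) %*% c(1.5, -0.5, 1))
  dat <- make_switching_var(2000, list(A), list(dr), dwell = 1e9,
                            noise_sd = 0.1, seed = 2)
  m <- fit_ar_only(dat$latents, n_states = 1, ar_order = 1, iters = 20,
                   seed = 1)
  C_hat <- m$C[[1]]
  expect_lt(norm(C_hat[, 1:3] - A, "F"), 0.1)
  expect_lt(sqrt(sum((C_hat[, 4] - dr)^2)), 0.1)
  # log-likelihood is non-decreasing over EM iterations
  expect_true(all(diff(m$logliks) > -1e-6))
})

test_that("iters = 0 returns the initialization unchanged", {
  dat <- two_state_fixture()
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 0,
                    seed = 7)
  expect_length(m0$logliks, 0)
  m0b <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 0,
                     seed = 7)
  expect_equal(m0$C, m0b$C)
  expect_equal(m0$Pi, matrix(1 / 3, 3, 3))
})

test_that("degenerate constant latents are rejected", {
  flat <- cbind(rep(1, 100), rnorm(100), rnorm(100))
  expect_error(fit_ar_only(flat, n_states = 2), "singularity")
  expect_error(fit_ar_only(matrix(rnorm(9), 3, 3), ar_order = 5), "frames")
})

test_that("three-state switching dynamics are segmented accurately", {
  A <- list(0.92 * rot3(c(0, 0, 1), 0.2),
            0.92 * rot3(c(1, 0, 0), 0.5),
            0.92 * rot3(c(0, 1, 0), 0.9))
  att <- list(c(2.5, 0, 0), c(-2, 2, 0), c(0, -2, 2))
  dr <- lapply(1:3, function(k) as.numeric((diag(3) - A[[k]]) %*% att[[k]]))
  dat <- make_switching_var(6000, A, dr, dwell = 60, noise_sd = 0.1,
                            seed = 11)
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 30,
                    seed = 1)
  fit <- fit_full(m0, dat$latents, iters = 200)
  al <- align_states(fit$sequence$states, dat$states)
  expect_gte(al$accuracy, 0.85)
  # AR coefficient recovery after state alignment
  for (true_k in seq_len(3)) {
    est_k <- unname(al$mapping[as.character(true_k)])
    expect_lt(norm(fit$model$C[[est_k]][, 1:3] - A[[true_k]], "F"), 0.1)
  }
  # usage bookkeeping: per-state counts partition the frames
  expect_equal(sum(fit$sequence$usage), 6000)
  expect_equal(sum(fit$sequence$durations), 6000)
})

test_that("infinite stickiness collapses the decoding to one syllable", {
  dat <- two_state_fixture()
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 10,
                    seed = 3)
  expect_warning(fit <- fit_full(m0, dat$latents, iters = 20, kappa = Inf),
                 "single state")
  expect_equal(fit$sequence$n_syllables, 1)
  expect_equal(length(fit$sequence$durations), 1)
})

test_that("bout count is non-increasing in the stickiness weight", {
  dat <- two_state_fixture()
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 10,
                    seed = 3)
  bouts <- vapply(c(1e2, 1e5, 1e8, 1e11, Inf), function(kp) {
    fit <- suppressWarnings(fit_full(m0, dat$latents, iters = 40,
                                     kappa = kp))
    length(fit$sequence$durations)
  }, numeric(1))
  expect_true(all(diff(bouts) <= 0))
})

test_that("multi-state fit predicts one step ahead better than single-state AR", {
  dat <- two_state_fixture()
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 20,
                    seed = 3)
  fit <- fit_full(m0, dat$latents, iters = 100)
  single <- fit_ar_only(dat$latents, n_states = 1, ar_order = 1, iters = 10,
                        seed = 3)
  expect_lt(onestep_error(fit$model, dat$latents),
            onestep_error(single, dat$latents))
})

test_that("decoded reports are invariant to state relabeling", {
  dat <- two_state_fixture()
  m0 <- fit_ar_only(dat$latents, n_states = 3, ar_order = 1, iters = 15,
                    seed = 4)
  fit <- fit_full(m0, dat$latents, iters = 60)
  al <- align_states(fit$sequence$states, dat$states)
  # aligning against a relabeled reference gives the same accuracy
  relab <- c(2L, 1L)[dat$states]
  al2 <- align_states(fit$sequence$states, relab)
  expect_equal(al$accuracy, al2$accuracy)
})

test_that("syllable statistics summarize speed ratios and handle windows", {
  trial <- selective_trial()
  # build a two-syllable sequence from ground truth: motif 1 vs everything
  seq_states <- ifelse(trial$states == 0, 1L, 2L)
  sseq <- syllable_sequence(seq_states)
  stats <- syllable_statistics(sseq, trial$series, window = 30)
  expect_equal(nrow(stats$table), 2)
  # rest frames are slower than stimulation frames
  sp <- stats$table$mean_speed[order(stats$table$syllable)]
  expect_lt(sp[1], sp[2])

  # one syllable spanning all frames: mean vector equals the grand mean
  all_one <- syllable_sequence(rep(1L, nrow(trial$series$x)))
  s1 <- syllable_statistics(all_one, trial$series,
                            window = nrow(trial$series$x))
  expect_equal(unname(s1$vectors[1, ]),
               unname(colMeans(cbind(trial$series$x, trial$series$y))))

  # window longer than the shortest bout: truncated averaging still works
  s2 <- syllable_statistics(sseq, trial$series, window = 10000)
  expect_false(anyNA(s2$vectors))
})

test_that("cosine dendrogram distances hit the canonical values", {
  u <- c(1, 0, 0, 0)
  m <- rbind(a = u, b = u, c = c(0, 1, 0, 0), d = -u)
  d <- as.matrix(cosine_distances(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], 2)
  expect_error(cosine_distances(rbind(u, rep(0, 4))), "zero-norm")
  dd <- syllable_dendrogram(m)
  expect_s3_class(dd$hclust, "hclust")
  expect_error(syllable_dendrogram(m[1, , drop = FALSE]), "at least 2")
})

test_that("selective syllables are mutually more distinct than nonselective ones", {
  # compare evoked movement syllables (mostly-ON states); rest-dominated
  # syllables would contribute identical rest-vs-movement contrasts to both
  # regimes and mask the difference in movement variety
  dist_for <- function(trial) {
    prep <- trial$prep
    lat <- pca_latents(prep$values)
    m0 <- fit_ar_only(lat, n_states = 12, seed = 1, iters = 30)
    fit <- fit_full(m0, lat, iters = 150)
    stats <- suppressMessages(
      syllable_statistics(fit$sequence, trial$series))
    on_frac <- vapply(stats$table$syllable, function(s)
      mean(!is.na(prep$labels[fit$sequence$states == s])), numeric(1))
    mean(cosine_distances(
      stats$offset_vectors[on_frac > 0.5, , drop = FALSE]))
  }
  expect_gt(dist_for(selective_trial()), dist_for(nonselective_trial()))
})
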