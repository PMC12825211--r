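make_epochs <- function(n, on_f = 100, off_f = 50, labels = seq_len(n)) {
  step <- on_f + off_f
  epoch_table(data.frame(
    label = as.integer(labels), mode = "BP2",
    on_start = (seq_len(n) - 1L) * step, on_end = (seq_len(n) - 1L) * step + on_f,
    off_start = (seq_len(n) - 1L) * step + on_f,
    off_end = seq_len(n) * step, subject_id = "S1"))
}

test_that("syllable-by-configuration proportions are normalized per configuration", {
  ep <- make_epochs(2)
  states <- integer(300)
  states[1:100] <- 3L                      # config 1: all syllable 3
  states[101:150] <- 9L                    # rest
  states[151:250] <- rep(c(1L, 2L), 50)    # config 2: 50/50 split
  states[251:300] <- 9L
  tab <- syllable_config_table(states, ep)
  expect_equal(unname(tab$p["1", "3"]), 1)
  expect_equal(unname(tab$p["2", c("1", "2")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(tab$p)), c(1, 1))
  expect_equal(tab$n_syllables, 3)  # syllables 1, 2, 3 during ON frames

  # gated-out configurations are absent from the table
  ep2 <- ep; ep2$retained <- c(FALSE, TRUE)
  tab2 <- syllable_config_table(states, ep2)
  expect_equal(rownames(tab2$counts), "2")
  expect_equal(tab2$excluded, 1L)

  # bout-based counting collapses repeated frames into occurrences
  tab3 <- syllable_config_table(states, ep, unit = "bouts")
  expect_equal(unname(tab3$counts["2", c("1", "2")]), c(50L, 50L))
  expect_equal(unname(tab3$counts["1", "3"]), 1L)
})

test_that("selectivity score spans its analytic anchor cases", {
  ep <- make_epochs(3)
  states <- integer(450)
  states[1:100] <- 1L                        # single syllable -> score 1
  states[101:150] <- 9L
  states[151:250] <- rep(1:4, 25)            # uniform over N=4
  states[251:300] <- 9L
  states[301:400] <- rep(c(2L, 3L), 50)      # two of four -> 1 - ln2/ln4
  states[401:450] <- 9L
  sc <- selectivity_score(syllable_config_table(states, ep))
  expect_equal(sc$score[sc$label == 1], 1)
  expect_equal(sc$score[sc$label == 2], 0)
  expect_equal(sc$score[sc$label == 3], 0.5)
  expect_equal(sc$entropy[sc$label == 3], log(2))

  # N = 1: defined as 1 with a warning
  one <- integer(150); one[1:100] <- 5L; one[101:150] <- 5L
  expect_warning(sc1 <- selectivity_score(
    syllable_config_table(one, make_epochs(1))), "single syllable")
  expect_equal(sc1$score, 1)
})

test_that("score is invariant to syllable relabeling and anti-monotone in entropy", {
  ep <- make_epochs(2)
  states <- integer(300)
  states[1:100] <- rep(c(1L, 2L), 50)
  states[151:250] <- rep(c(3L, 4L), c(80, 20))
  sc <- selectivity_score(syllable_config_table(states, ep))
  relab <- states
  relab[states == 1] <- 7L; relab[states == 2] <- 1L
  relab[states == 3] <- 8L; relab[states == 4] <- 3L
  sc_r <- selectivity_score(syllable_config_table(relab, ep))
  expect_equal(sc$score, sc_r$score)
  # spreading mass from a dominant syllable lowers the score
  expect_gt(sc$score[sc$label == 2], sc$score[sc$label == 1])

  # base invariance: natural-log score equals a log2 recomputation
  tab <- syllable_config_table(states, ep)
  p <- tab$p["2", ]; p <- p[p > 0]
  score_log2 <- 1 - (-sum(p * log2(p))) / log2(tab$n_syllables)
  expect_equal(sc$score[sc$label == 2], unname(score_log2),
               tolerance = 1e-12)
})

test_that("bootstrap means are reproducible with calibrated intervals", {
  # constant scores: degenerate CI
  bs <- bootstrap_means(rep(0.7, 50), rep("g", 50), m = 100, B = 200,
                        seed = 1)
  expect_equal(bs$summary$boot_mean, 0.7)
  expect_equal(bs$summary$ci_lo, 0.7)
  expect_equal(bs$summary$ci_hi, 0.7)

  # same seed reproduces exactly
  sc <- runif(80); gr <- rep(c("a", "b"), 40)
  expect_identical(bootstrap_means(sc, gr, seed = 5),
                   bootstrap_means(sc, gr, seed = 5))
  expect_error(bootstrap_means(sc, gr, m = 0), "at least 1")

  # unbalanced beta-distributed groups with mean 0.79 vs 0.63 separate:
  # the 95% intervals of the resampled means do not overlap
  set.seed(8)
  scores <- c(rbeta(676, 0.79 * 10, 0.21 * 10),
              rbeta(164, 0.63 * 10, 0.37 * 10))
  grp <- rep(c("TIS", "Biphasic"), c(676, 164))
  bs2 <- bootstrap_means(scores, grp, m = 100, B = 1000, seed = 1)
  expect_false(bs2$ci_overlap)
  expect_equal(bs2$summary$boot_mean[bs2$summary$group == "TIS"], 0.79,
               tolerance = 0.02)
})

test_that("beta regression agrees with a direct ML oracle on a fixture", {
  set.seed(31)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  mu <- plogis(-0.4 + 1.1 * x)
  y <- rbeta(n, mu * 12, (1 - mu) * 12)
  df <- data.frame(score = y, x = factor(x))
  fit <- beta_regression(score ~ x, df)
  # oracle works on the same compressed response the package fits
  yc <- (y * (n - 1) + 0.5) / n
  orc <- beta_mle_oracle(cbind(1, x), yc)
  expect_equal(orc$convergence, 0)
  expect_equal(unname(fit$coefficients$estimate), unname(orc$coef),
               tolerance = 1e-4)
  expect_equal(fit$phi, orc$phi, tolerance = 1e-3)
})

test_that("beta regression validates inputs and handles null effects", {
  df <- data.frame(score = c(-0.1, 0.5), g = factor(c("a", "b")))
  expect_error(beta_regression(score ~ g, df), "\\[0, 1\\]")
  # equal constant groups: group coefficient near zero
  set.seed(2)
  df2 <- data.frame(score = rep(0.5, 80) + rnorm(80, sd = 1e-3),
                    g = factor(rep(c("a", "b"), 40)))
  fit <- beta_regression(score ~ g, df2)
  expect_lt(abs(fit$coefficients$estimate[2]), 0.05)
})

test_that("nonparametric effects match their defining formulas", {
  x <- c(1, 2, 3, 4)
  same <- nonparametric_effects(x, x)
  expect_equal(same$cohen_d, 0)
  expect_equal(same$cliffs_delta, 0)

  expect_equal(nonparametric_effects(c(1, 1), c(0, 0))$cliffs_delta, 1)
  # enumerated oracle: a = {3,4,5}, b = {1,2,3} -> (8 - 0) / 9
  expect_equal(cliffs_delta(c(3, 4, 5), c(1, 2, 3)), 8 / 9)
  expect_equal(cliffs_delta_bruteforce(c(3, 4, 5), c(1, 2, 3)), 8 / 9)

  # U and p equal the reference test
  set.seed(3)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  got <- nonparametric_effects(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_error(nonparametric_effects(1, c(1, 2)), "at least 2")
})

test_that("fast Cliff's delta equals brute force on random tied groups", {
  set.seed(9)
  for (r in 1:50) {
    a <- sample(0:5, sample(2:20, 1), replace = TRUE)
    b <- sample(0:5, sample(2:20, 1), replace = TRUE)
    expect_equal(cliffs_delta(a, b), cliffs_delta_bruteforce(a, b))
  }
})
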