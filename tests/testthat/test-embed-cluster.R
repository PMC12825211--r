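test_that("AMI is exact on identical partitions and label-permutation invariant", {
  expect_equal(ami(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ami(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # symmetry and the brute-force value on a crossed labeling
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  expect_equal(ami(a, b), ami(b, a))
  expect_equal(ami(a, b), ami_bruteforce(a, b), tolerance = 1e-9)
  # single class in both labelings: 1 by convention
  expect_equal(ami(c(2, 2, 2), c(5, 5, 5)), 1)
})

test_that("AMI matches the permutation-enumeration oracle on small instances", {
  # exhaustive over all 2-class labelings of length 4
  grid4 <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (i in seq_len(nrow(grid4))) for (j in seq_len(nrow(grid4))) {
    a <- grid4[i, ]; b <- grid4[j, ]
    expect_equal(ami(a, b), ami_bruteforce(a, b), tolerance = 1e-9)
  }
  # random 3-class labelings up to length 7
  set.seed(42)
  for (n in 5:7) for (r in 1:20) {
    a <- sample.int(3, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    expect_equal(ami(a, b), ami_bruteforce(a, b), tolerance = 1e-9)
  }
})

test_that("AMI stays at most 1 and near 0 for independent labelings", {
  set.seed(7)
  vals <- replicate(200, {
    a <- sample.int(3, 40, replace = TRUE)
    b <- sample.int(3, 40, replace = TRUE)
    ami(a, b)
  })
  expect_true(all(vals <= 1 + 1e-12))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("embedding profiles carry the published hyperparameters", {
  bi <- embed_profile("biphasic")
  expect_equal(bi$n_neighbors, 50)
  expect_equal(bi$min_dist, 0)
  expect_equal(bi$n_components, 3)
  expect_equal(bi$min_cluster_size, 30)
  expect_equal(bi$min_samples, 5)
  expect_equal(bi$cluster_selection_epsilon, 1)
  ti <- embed_profile("tis")
  expect_equal(ti$n_neighbors, 177)
  expect_equal(ti$min_cluster_size, 128)
  expect_equal(ti$min_samples, 300)
})

test_that("embedding separates well-separated motifs and validates sizes", {
  trial <- tiny_trial()
  emb <- embed(trial$prep$values)
  expect_equal(dim(emb$coords), c(nrow(trial$prep$values), 3))
  expect_true(all(is.finite(emb$coords)))
  st <- trial$states
  c1 <- colMeans(emb$coords[st == 1, , drop = FALSE])
  c2 <- colMeans(emb$coords[st == 2, , drop = FALSE])
  spread <- mean(c(apply(emb$coords[st == 1, ], 2, sd),
                   apply(emb$coords[st == 2, ], 2, sd)))
  expect_gt(sqrt(sum((c1 - c2)^2)), spread)

  expect_error(embed(trial$prep$values[1:20, ]), "n_neighbors")
})

test_that("density clustering recovers separated blobs and flags sparse noise", {
  set.seed(1)
  blob1 <- matrix(rnorm(1500, sd = 0.3), 500, 3)
  blob2 <- matrix(rnorm(1500, sd = 0.3), 500, 3) + 20
  lab <- cluster_density(rbind(blob1, blob2), profile = "biphasic")
  expect_equal(length(setdiff(unique(lab), -1L)), 2)
  # blob membership is pure after noise removal
  expect_equal(length(unique(lab[1:500][lab[1:500] != -1])), 1)
  expect_equal(length(unique(lab[501:1000][lab[501:1000] != -1])), 1)

  sparse <- matrix(runif(120, 0, 100), 40, 3)
  expect_warning(lab_s <- cluster_density(sparse, profile = "biphasic"),
                 "noise")
  expect_true(all(lab_s == -1L))

  few <- matrix(rnorm(30), 10, 3)
  expect_warning(lab_f <- cluster_density(few, profile = "tis"),
                 "min_cluster_size")
  expect_true(all(lab_f == -1L))
})

test_that("k-means baseline covers the degenerate k values", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(300, sd = 0.2), 100, 3),
               matrix(rnorm(300, sd = 0.2), 100, 3) + 5)
  expect_equal(unique(cluster_kmeans(pts, 1)), 0L)
  k2 <- cluster_kmeans(pts, 2)
  expect_equal(length(unique(k2[1:100])), 1)
  expect_equal(length(unique(k2[101:200])), 1)
  expect_false(k2[1] == k2[101])
  kT <- cluster_kmeans(pts, nrow(pts))
  expect_equal(sort(unique(kT)), 0:(nrow(pts) - 1))
  expect_error(cluster_kmeans(pts, 201), "between 1")
  # fixed seed reproducibility
  expect_identical(cluster_kmeans(pts, 2, seed = 9),
                   cluster_kmeans(pts, 2, seed = 9))
})

test_that("null controls preserve shape and their respective invariants", {
  vals <- selective_trial()$prep$values
  shuf <- null_controls(vals, "row_shuffle", seed = 3)
  expect_equal(dim(shuf), dim(vals))
  # the multiset of rows is preserved
  o1 <- vals[do.call(order, as.data.frame(vals)), ]
  o2 <- shuf[do.call(order, as.data.frame(shuf)), ]
  expect_equal(unname(o1), unname(o2))
  # sigma multiplier 0 is the identity
  expect_equal(null_controls(vals, "gaussian_noise", seed = 3,
                             sigma_mult = 0), vals)
  # same seed reproduces, different seeds differ
  expect_identical(null_controls(vals, "gaussian_noise", seed = 3),
                   null_controls(vals, "gaussian_noise", seed = 3))
  expect_false(identical(null_controls(vals, "gaussian_noise", seed = 3),
                         null_controls(vals, "gaussian_noise", seed = 4)))
})

test_that("agreement on the nonselective regime is near zero (many-to-one map)", {
  trial <- nonselective_trial()
  emb <- embed(trial$prep$values)
  cl <- suppressWarnings(cluster_density(emb$coords))
  rep_ <- agreement_report(cl, trial$prep$labels, coords = emb$coords)
  expect_lt(rep_$ami, 0.15)
  expect_true(is.finite(rep_$silhouette))
  # contingency marginals add up to the scored frame count
  expect_equal(sum(rep_$contingency), rep_$n_used)
})

test_that("hyperparameter search returns the argmax and the full trace", {
  vals <- tiny_trial()$prep$values
  labels <- tiny_trial()$prep$labels
  one <- data.frame(n_neighbors = 30, min_cluster_size = 30,
                    min_samples = 40, cluster_selection_epsilon = 0.3)
  res1 <- suppressWarnings(
    tune_hyperparams(vals, one, objective = "ami", config_labels = labels))
  expect_equal(res1$best$n_neighbors, 30)
  expect_equal(nrow(res1$trace), 1)

  space <- rbind(one, transform(one, cluster_selection_epsilon = 5))
  res <- suppressWarnings(
    tune_hyperparams(vals, space, objective = "combined",
                     config_labels = labels))
  expect_true(res$best_objective >= max(res$trace$objective) - 1e-12)
  expect_equal(nrow(res$trace), 2)

  expect_error(tune_hyperparams(vals, one[0, ], objective = "ami",
                                config_labels = labels), "empty")
})
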