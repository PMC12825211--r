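# The clustering arm: 3-D nonlinear embedding of the position matrix,
# density-based clustering, a k-means baseline, agreement scoring against
# configuration labels, null controls, and hyperparameter search.
#
# The embedding is a kNN-graph spectral embedding (Laplacian eigenmap):
# a symmetrized k-nearest-neighbour graph with self-tuning Gaussian edge
# weights is built on the standardized position matrix and the leading
# non-trivial eigenvectors of its normalized adjacency give the 3-D
# coordinates. Like other manifold embedders, its key parameter is the
# neighbourhood size; the per-paradigm presets keep the published
# neighbourhood sizes. The density clusterer connects points whose mutual
# reachability distance (the pairwise distance floored by both points' core
# distances) is within `cluster_selection_epsilon`, discards components
# smaller than `min_cluster_size`, and labels unassigned points -1.

#' Embedding / clustering parameter presets
#'
#' Per-paradigm presets: `"biphasic"` uses neighbourhood size 50,
#' `min_dist` 0, and density-clustering settings (30, 5, epsilon 1);
#' `"tis"` uses neighbourhood size 177 with stricter clustering
#' (128, 300). Those two are tuned to in-vivo recording sizes; `"custom"`
#' carries the defaults used for desk-scale synthetic trials.
#'
#' @param profile `"biphasic"`, `"tis"`, or `"custom"`.
#' @return Named list of parameters.
#' @export
embed_profile <- function(profile = c("custom", "biphasic", "tis")) {
  profile <- match.arg(profile)
  switch(profile,
    biphasic = list(n_neighbors = 50, min_dist = 0, n_components = 3,
                    min_cluster_size = 30, min_samples = 5,
                    cluster_selection_epsilon = 1),
    tis = list(n_neighbors = 177, min_dist = 0, n_components = 3,
               min_cluster_size = 128, min_samples = 300,
               cluster_selection_epsilon = 1),
    custom = list(n_neighbors = 30, min_dist = 0, n_components = 3,
                  min_cluster_size = 30, min_samples = 40,
                  cluster_selection_epsilon = 0.3))
}

# Exact k-nearest-neighbour search (brute force, compiled).
knn_dist <- function(values, k) {
  values <- as.matrix(values)
  if (k >= nrow(values))
    stop("n_neighbors must be smaller than the number of frames")
  knn_brute(values, as.integer(k))
}

#' Spectral (Laplacian-eigenmap) embedding of a position matrix
#'
#' Builds a symmetrized kNN graph with self-tuning Gaussian weights and
#' embeds it into `n_components` dimensions using the leading non-trivial
#' eigenvectors of the normalized adjacency (ARPACK). Each output dimension
#' is scaled to unit SD so that distance-based clustering thresholds are
#' comparable across trials. Embedding is intended to be run per animal.
#'
#' @param values Standardized T x K position matrix.
#' @param profile Parameter preset name (see [embed_profile()]).
#' @param n_neighbors Override the preset neighbourhood size.
#' @param seed Seed for the (deterministically initialized) eigensolver;
#'   kept for interface stability, the embedding is deterministic.
#' @return List of class `embedding_result`: `coords` (T x 3), `params`.
#' @export
embed <- function(values, profile = "custom", n_neighbors = NULL, seed = 42) {
  params <- embed_profile(profile)
  if (!is.null(n_neighbors)) params$n_neighbors <- n_neighbors
  n <- nrow(values)
  if (n <= params$n_neighbors)
    stop("n_neighbors (", params$n_neighbors,
         ") must be smaller than the number of frames (", n, ")")
  nn <- knn_dist(values, params$n_neighbors)
  # self-tuning bandwidth: each point's distance to its k-th neighbour
  sigma <- nn$dist[, ncol(nn$dist)]
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-8)
  i <- rep(seq_len(n), each = ncol(nn$index))
  j <- as.integer(t(nn$index))
  d <- as.numeric(t(nn$dist))
  w <- exp(-d^2 / (sigma[i] * sigma[j]))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  deg <- Matrix::rowSums(A)
  deg[deg <= 0] <- 1e-12
  dis <- 1 / sqrt(deg)
  M <- A * tcrossprod(dis)   # D^{-1/2} A D^{-1/2}, still sparse pattern
  nev <- params$n_components + 1
  set.seed(seed)
  ar <- igraph::arpack(function(x, extra) as.numeric(extra %*% x), extra = M,
                       sym = TRUE,
                       options = list(n = n, nev = nev,
                                      ncv = max(3 * nev, 20),
                                      which = "LA", maxiter = 5000))
  vec <- ar$vectors[, order(ar$values, decreasing = TRUE), drop = FALSE]
  coords <- vec[, 2:nev, drop = FALSE] * dis
  coords <- scale(coords, center = TRUE, scale = apply(coords, 2, sd))
  coords[!is.finite(coords)] <- 0
  structure(list(coords = unname(coords[, , drop = FALSE]), params = params),
            class = "embedding_result")
}

#' Density-based clustering of embedded coordinates
#'
#' Core distances are each point's distance to its `min_samples`-th
#' neighbour; two points are density-connected when their mutual
#' reachability distance `max(core_i, core_j, d_ij)` is at most
#' `cluster_selection_epsilon`. Connected components of the density graph
#' with at least `min_cluster_size` members become clusters (labels `0..C-1`
#' in decreasing size order); all other points are noise (`-1`).
#'
#' @param coords T x d coordinate matrix (embedding output).
#' @param profile Preset name supplying defaults (see [embed_profile()]).
#' @param min_cluster_size,min_samples,cluster_selection_epsilon Overrides.
#' @param k_graph Neighbourhood size of the density-connectivity graph.
#' @return Integer label vector (`-1` = noise).
#' @export
cluster_density <- function(coords, profile = "custom",
                            min_cluster_size = NULL, min_samples = NULL,
                            cluster_selection_epsilon = NULL,
                            k_graph = NULL) {
  params <- embed_profile(profile)
  mcs <- min_cluster_size %||% params$min_cluster_size
  ms <- min_samples %||% params$min_samples
  eps <- cluster_selection_epsilon %||% params$cluster_selection_epsilon
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < mcs) {
    warning("fewer points (", n, ") than min_cluster_size (", mcs,
            "): all points labeled noise")
    return(rep(-1L, n))
  }
  k <- min(n - 1L, k_graph %||% max(4L * ms, 32L))
  nn <- knn_dist(coords, k)
  core <- nn$dist[, min(ms, k)]
  i <- rep(seq_len(n), each = k)
  j <- as.integer(t(nn$index))
  d <- as.numeric(t(nn$dist))
  mreach <- pmax(d, core[i], core[j])
  keep <- mreach <= eps & core[i] <= eps & core[j] <= eps
  labels <- rep(-1L, n)
  if (any(keep)) {
    g <- igraph::graph_from_edgelist(cbind(i[keep], j[keep]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    sizes <- tabulate(comp$membership)
    big <- which(sizes >= mcs)
    big <- big[order(sizes[big], decreasing = TRUE)]
    for (ci in seq_along(big))
      labels[comp$membership == big[ci]] <- ci - 1L
  }
  if (all(labels == -1L))
    warning("density clustering found no cluster; all points are noise")
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' K-means baseline clustering
#'
#' @param coords T x d coordinate matrix.
#' @param k Number of clusters (1 <= k <= T).
#' @param seed Seed for the stochastic initialization.
#' @return Integer label vector (`0..k-1`).
#' @export
cluster_kmeans <- function(coords, k, seed = 42) {
  coords <- as.matrix(coords)
  if (k < 1 || k > nrow(coords))
    stop("k must be between 1 and the number of points")
  if (k == nrow(coords)) return(seq_len(nrow(coords)) - 1L)
  set.seed(seed)
  km <- kmeans(coords, centers = k, nstart = 10, iter.max = 50)
  as.integer(km$cluster) - 1L
}

#' Null controls for the clustering arm
#'
#' `"row_shuffle"` permutes the frame rows of the position matrix, breaking
#' the correspondence between movement dynamics and stimulation epochs while
#' preserving the multiset of poses. `"gaussian_noise"` adds independent
#' N(0, (sigma_mult * column SD)^2) noise to every cell. Either control,
#' re-run through embedding and clustering, should abolish agreement with
#' the configuration labels if that agreement reflects real structure.
#'
#' @param values T x K position matrix.
#' @param mode `"row_shuffle"` or `"gaussian_noise"`.
#' @param seed Integer seed.
#' @param sigma_mult Noise SD as a multiple of each column's SD (default 1).
#' @return A position matrix of the same shape.
#' @export
null_controls <- function(values, mode = c("row_shuffle", "gaussian_noise"),
                          seed = 1, sigma_mult = 1) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  set.seed(seed)
  if (mode == "row_shuffle") {
    values[sample.int(nrow(values)), , drop = FALSE]
  } else {
    if (sigma_mult == 0) return(values)
    sds <- apply(values, 2, sd) * sigma_mult
    values + matrix(rnorm(length(values)), nrow(values)) %*% diag(sds)
  }
}

#' Cluster-vs-configuration agreement report
#'
#' @param cluster_labels Integer labels (`-1` = noise).
#' @param config_labels Per-frame configuration labels (`NA` = rest frames,
#'   which are excluded).
#' @param coords Optional coordinates for the silhouette score.
#' @param max_silhouette_n Silhouette is computed on an evenly spaced
#'   subsample of at most this many points (the full pairwise distance
#'   matrix is quadratic in frames).
#' @return List of class `agreement_report`: `ami`, `silhouette` (NA when
#'   not computable), `contingency` (clusters x configurations), `n_used`.
#' @export
agreement_report <- function(cluster_labels, config_labels, coords = NULL,
                             max_silhouette_n = 2000) {
  keep <- !is.na(config_labels) & cluster_labels != -1L
  sil <- NA_real_
  if (!is.null(coords)) {
    kc <- which(cluster_labels != -1L)
    if (length(kc) > max_silhouette_n)
      kc <- kc[round(seq(1, length(kc), length.out = max_silhouette_n))]
    if (length(unique(cluster_labels[kc])) >= 2) {
      s <- cluster::silhouette(as.integer(as.factor(cluster_labels[kc])),
                               dist(as.matrix(coords)[kc, , drop = FALSE]))
      sil <- mean(s[, "sil_width"])
    }
  }
  if (sum(keep) < 2 || length(unique(cluster_labels[keep])) < 1)
    return(structure(list(ami = 0, silhouette = sil, contingency = NULL,
                          n_used = sum(keep)), class = "agreement_report"))
  structure(list(
    ami = ami(cluster_labels[keep], config_labels[keep],
              exclude_noise = FALSE),
    silhouette = sil,
    contingency = table(cluster = cluster_labels[keep],
                        configuration = config_labels[keep]),
    n_used = sum(keep)), class = "agreement_report")
}

#' Grid search over embedding / clustering hyperparameters
#'
#' Evaluates every row of `search_space` (columns may include
#' `n_neighbors`, `min_cluster_size`, `min_samples`,
#' `cluster_selection_epsilon`) by embedding, clustering, and scoring with
#' the chosen objective: mean silhouette width, AMI against `config_labels`,
#' or their combination `mean((silhouette + 1) / 2, ami)`.
#'
#' @param values Standardized position matrix.
#' @param search_space Data frame of parameter combinations (non-empty).
#' @param objective `"silhouette"`, `"ami"`, or `"combined"`.
#' @param config_labels Per-frame configuration labels (required for the
#'   `ami` and `combined` objectives).
#' @param seed Embedding seed.
#' @return List with `best` (the argmax row, as a list), `best_objective`,
#'   and `trace` (the search space with an `objective` column).
#' @export
tune_hyperparams <- function(values, search_space,
                             objective = c("silhouette", "ami", "combined"),
                             config_labels = NULL, seed = 42) {
  objective <- match.arg(objective)
  search_space <- as.data.frame(search_space)
  if (nrow(search_space) == 0) stop("empty hyperparameter search space")
  if (objective != "silhouette" && is.null(config_labels))
    stop("config_labels required for the ", objective, " objective")
  scores <- vapply(seq_len(nrow(search_space)), function(r) {
    p <- as.list(search_space[r, , drop = FALSE])
    emb <- embed(values, n_neighbors = p$n_neighbors %||% NULL, seed = seed)
    lab <- cluster_density(
      emb$coords,
      min_cluster_size = p$min_cluster_size %||% NULL,
      min_samples = p$min_samples %||% NULL,
      cluster_selection_epsilon = p$cluster_selection_epsilon %||% NULL)
    rep_ <- agreement_report(lab, config_labels, coords = emb$coords)
    sil01 <- if (is.na(rep_$silhouette)) 0 else (rep_$silhouette + 1) / 2
    switch(objective,
           silhouette = if (is.na(rep_$silhouette)) -Inf else rep_$silhouette,
           ami = rep_$ami,
           combined = mean(c(sil01, rep_$ami)))
  }, numeric(1))
  best <- which.max(scores)
  trace <- search_space
  trace$objective <- scores
  list(best = as.list(search_space[best, , drop = FALSE]),
       best_objective = scores[best], trace = trace)
}
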