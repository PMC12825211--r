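# Sticky autoregressive hidden Markov segmentation of movement into
# behavioral syllables. The model is a weak-limit finite sticky HMM: up to
# K_max states, each with a vector-autoregressive emission of order
# `ar_order` in a 3-D latent space obtained by principal components of the
# position matrix. Stickiness enters as a Dirichlet pseudo-count `kappa` on
# the transition-matrix diagonal, discouraging state switches; fitting
# follows the two-phase protocol (an AR-only phase under a near-degenerate
# sticky prior, then a full phase jointly refining AR parameters and the
# segmentation), implemented as EM with a deterministic Viterbi decode.

#' Project a position matrix to latent coordinates
#'
#' Principal-component projection of the (standardized) T x K position
#' matrix to `d` dimensions — the low-dimensional pose representation the
#' syllable model is fit in.
#'
#' @param values T x K position matrix.
#' @param d Latent dimension (default 3).
#' @return T x d matrix with the rotation stored as attribute `rotation`.
#' @export
pca_latents <- function(values, d = 3) {
  p <- prcomp(values, center = TRUE, scale. = FALSE)
  out <- p$x[, seq_len(d), drop = FALSE]
  attr(out, "rotation") <- p$rotation[, seq_len(d), drop = FALSE]
  out
}

# Stacked-lag design: row t predicts x_t from [x_{t-1}, ..., x_{t-r}, 1].
ar_design <- function(latents, r) {
  T_n <- nrow(latents); d <- ncol(latents)
  X <- latents[(r + 1):T_n, , drop = FALSE]
  U <- matrix(1, T_n - r, d * r + 1)
  for (l in seq_len(r))
    U[, ((l - 1) * d + 1):(l * d)] <- latents[(r + 1 - l):(T_n - l), ,
                                              drop = FALSE]
  list(X = X, U = U)
}

# Per-state Gaussian VAR log density for every frame.
ar_loglik_matrix <- function(des, C, Sigma) {
  K <- length(C); d <- ncol(des$X)
  out <- matrix(0, nrow(des$X), K)
  for (k in seq_len(K)) {
    resid <- des$X - des$U %*% t(C[[k]])
    R <- chol(Sigma[[k]])
    z <- resid %*% backsolve(R, diag(d))
    out[, k] <- -0.5 * rowSums(z^2) - sum(log(diag(R))) -
      0.5 * d * log(2 * pi)
  }
  out
}

# Weighted VAR refit for one state; returns NULL when the state has too
# little responsibility mass to identify its parameters.
ar_wls <- function(des, w, ridge = 1e-8) {
  d <- ncol(des$X); p <- ncol(des$U)
  if (sum(w) < p + d + 1) return(NULL)
  Uw <- des$U * w
  G <- crossprod(des$U, Uw) + ridge * diag(p)
  Ct <- solve(G, crossprod(Uw, des$X))
  C <- t(Ct)
  resid <- des$X - des$U %*% Ct
  Sigma <- crossprod(resid * sqrt(w)) / sum(w) + 1e-6 * diag(d)
  list(C = C, Sigma = Sigma)
}

sticky_transitions <- function(xi, kappa) {
  K <- nrow(xi)
  if (is.infinite(kappa)) return(diag(K))
  P <- xi + kappa * diag(K) + 1e-3
  P / rowSums(P)
}

arhmm_init <- function(latents, n_states, ar_order, seed) {
  set.seed(seed)
  des <- ar_design(latents, ar_order)
  feats <- cbind(des$X, des$X - des$U[, seq_len(ncol(des$X)), drop = FALSE])
  km <- kmeans(feats, centers = min(n_states, nrow(feats) - 1),
               nstart = 5, iter.max = 30)
  assign <- km$cluster
  C <- vector("list", n_states); Sigma <- vector("list", n_states)
  d <- ncol(des$X); p <- ncol(des$U)
  pooled <- ar_wls(des, rep(1, nrow(des$X)))
  for (k in seq_len(n_states)) {
    fit <- ar_wls(des, as.numeric(assign == k))
    if (is.null(fit)) fit <- list(C = pooled$C + matrix(rnorm(d * p, sd = 0.01),
                                                        d, p),
                                  Sigma = pooled$Sigma)
    C[[k]] <- fit$C; Sigma[[k]] <- fit$Sigma
  }
  list(C = C, Sigma = Sigma,
       Pi = matrix(1 / n_states, n_states, n_states),
       pi0 = rep(1 / n_states, n_states))
}

arhmm_em <- function(model, des, iters, kappa, tol = 1e-6) {
  logliks <- model$logliks %||% numeric(0)
  if (iters > 0) {
    for (it in seq_len(iters)) {
      logB <- ar_loglik_matrix(des, model$C, model$Sigma)
      fb <- forward_backward(logB, log(model$Pi), log(model$pi0 + 1e-300))
      logliks <- c(logliks, fb$loglik)
      for (k in seq_along(model$C)) {
        fit <- ar_wls(des, fb$gamma[, k])
        if (!is.null(fit)) { model$C[[k]] <- fit$C; model$Sigma[[k]] <- fit$Sigma }
      }
      model$Pi <- sticky_transitions(fb$xi, kappa)
      model$pi0 <- (fb$gamma[1, ] + 1e-6) / sum(fb$gamma[1, ] + 1e-6)
      n_ll <- length(logliks)
      if (n_ll >= 2 &&
          abs(logliks[n_ll] - logliks[n_ll - 1]) <
            tol * (abs(logliks[n_ll - 1]) + 1)) break
    }
  }
  model$logliks <- logliks
  model
}

#' AR-only fitting phase
#'
#' Learns the per-state autoregressive structure under a near-degenerate
#' sticky prior (`kappa` dominating the transition counts discourages state
#' switching while the AR parameters stabilize). Initialization is a seeded
#' k-means partition of position/velocity features; `iters = 0` returns the
#' initialization unchanged.
#'
#' @param latents T x d latent series (see [pca_latents()]).
#' @param n_states Maximum number of states (weak-limit truncation).
#' @param ar_order Autoregressive order (lags per state).
#' @param iters EM iterations (default 50).
#' @param kappa Sticky diagonal pseudo-count (default 1e9).
#' @param seed Seed for the initialization.
#' @param tol Relative log-likelihood convergence tolerance (early stop).
#' @return An object of class `arhmm_model` with per-state AR coefficient
#'   matrices `C`, noise covariances `Sigma`, transition matrix `Pi`,
#'   initial distribution `pi0`, and the log-likelihood trace `logliks`.
#' @export
fit_ar_only <- function(latents, n_states = 20, ar_order = 3, iters = 50,
                        kappa = 1e9, seed = 1, tol = 1e-6) {
  latents <- as.matrix(latents)
  if (nrow(latents) <= ar_order)
    stop("need more frames than the AR order")
  if (any(apply(latents, 2, sd) == 0))
    stop("covariance singularity: constant latent dimension(s)")
  des <- ar_design(latents, ar_order)
  model <- arhmm_init(latents, n_states, ar_order, seed)
  model$n_states <- n_states; model$ar_order <- ar_order
  model$d <- ncol(latents); model$kappa <- kappa
  model <- arhmm_em(model, des, iters, kappa, tol)
  class(model) <- "arhmm_model"
  model
}

#' Full fitting phase and syllable decoding
#'
#' Continues EM from an AR-only model, jointly refining AR parameters and
#' the segmentation under a (weaker) sticky prior, then decodes the final
#' state sequence deterministically with Viterbi. Empty states are dropped
#' from the reported syllable set and the remaining syllables relabeled
#' `1..S` in decreasing usage order; the first `ar_order` frames inherit the
#' first decoded state.
#'
#' @param model An `arhmm_model` from [fit_ar_only()].
#' @param latents The same latent series the model was initialized on.
#' @param iters EM iterations (default 500; stops early on convergence).
#' @param kappa Sticky pseudo-count for this phase (default 1e8;
#'   `Inf` forces a single uninterrupted syllable).
#' @param tol Relative log-likelihood convergence tolerance.
#' @return List with `model` (refined `arhmm_model`) and `sequence`
#'   (a `syllable_sequence`: `states` per frame, `durations` per bout,
#'   `usage` counts, `n_syllables`).
#' @export
fit_full <- function(model, latents, iters = 500, kappa = 1e8, tol = 1e-6) {
  stopifnot(inherits(model, "arhmm_model"))
  latents <- as.matrix(latents)
  des <- ar_design(latents, model$ar_order)
  model$logliks <- numeric(0)
  model <- arhmm_em(model, des, iters, kappa, tol)
  model$kappa <- kappa
  logB <- ar_loglik_matrix(des, model$C, model$Sigma)
  Pi <- sticky_transitions(
    forward_backward(logB, log(model$Pi), log(model$pi0 + 1e-300))$xi, kappa)
  path <- viterbi_path(logB, log(Pi), log(model$pi0 + 1e-300))
  states <- c(rep(path[1], model$ar_order), path)
  used <- sort(unique(states))
  if (length(used) == 1 && model$n_states > 1)
    warning("all frames decoded into a single state; kappa may be too high")
  # drop empty states and relabel by decreasing usage, keeping the model's
  # per-state parameters aligned with the new labels
  usage <- table(factor(states, levels = used))
  ord <- used[order(usage, decreasing = TRUE)]
  relabel <- setNames(seq_along(ord), ord)
  states <- as.integer(relabel[as.character(states)])
  model$C <- model$C[ord]
  model$Sigma <- model$Sigma[ord]
  model$Pi <- model$Pi[ord, ord, drop = FALSE]
  model$pi0 <- model$pi0[ord] / sum(model$pi0[ord])
  model$n_states <- length(ord)
  list(model = model, sequence = syllable_sequence(states))
}

#' Construct a syllable sequence summary
#'
#' @param states Integer per-frame syllable IDs.
#' @return Object of class `syllable_sequence` with `states`, `durations`
#'   (per-bout lengths, in frames), `bout_states`, `onsets` (0-based),
#'   `usage` (per-syllable frame counts), `n_syllables`.
#' @export
syllable_sequence <- function(states) {
  r <- rle(states)
  onsets <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  structure(list(states = states, durations = r$lengths,
                 bout_states = r$values, onsets = onsets,
                 usage = table(states),
                 n_syllables = length(unique(states))),
            class = "syllable_sequence")
}

#' One-step-ahead prediction error of a fitted model
#'
#' Mean squared norm of the one-step-ahead latent prediction residual along
#' the Viterbi path — the held-out comparison statistic between a
#' multi-state fit and a single-state AR baseline.
#'
#' @param model An `arhmm_model`.
#' @param latents T x d latent series.
#' @return Mean squared prediction error (latent units^2).
#' @export
onestep_error <- function(model, latents) {
  latents <- as.matrix(latents)
  des <- ar_design(latents, model$ar_order)
  logB <- ar_loglik_matrix(des, model$C, model$Sigma)
  path <- viterbi_path(logB, log(model$Pi), log(model$pi0 + 1e-300))
  err <- 0
  for (k in unique(path)) {
    idx <- path == k
    resid <- des$X[idx, , drop = FALSE] -
      des$U[idx, , drop = FALSE] %*% t(model$C[[k]])
    err <- err + sum(resid^2)
  }
  err / nrow(des$X)
}

#' Align estimated states to reference states
#'
#' Finds the label permutation maximizing frame-wise agreement (exhaustive
#' over permutations for up to 8 labels, greedy beyond) and reports the
#' aligned accuracy and mapping.
#'
#' @param estimated,reference Integer state vectors of equal length.
#' @return List with `accuracy` and `mapping` (named vector reference ->
#'   estimated).
#' @export
align_states <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference))
  es <- sort(unique(estimated)); rs <- sort(unique(reference))
  conf <- table(factor(estimated, es), factor(reference, rs))
  n_lab <- max(length(es), length(rs))
  if (n_lab <= 8) {
    perms <- all_permutations(length(es))
    best <- 0; best_perm <- seq_along(es)
    for (r in seq_len(nrow(perms))) {
      pm <- perms[r, ]
      hits <- sum(vapply(seq_along(es), function(i) {
        j <- pm[i]
        if (j <= length(rs)) conf[i, j] else 0
      }, numeric(1)))
      if (hits > best) { best <- hits; best_perm <- pm }
    }
    mapping <- setNames(es, rs[pmin(best_perm, length(rs))])
    acc <- best / length(estimated)
  } else {
    # greedy: repeatedly take the largest remaining confusion cell
    cf <- as.matrix(conf)
    mapping <- c(); hits <- 0
    while (any(cf > -1) && length(mapping) < min(dim(cf))) {
      ij <- which(cf == max(cf), arr.ind = TRUE)[1, ]
      hits <- hits + cf[ij[1], ij[2]]
      mapping <- c(mapping, setNames(es[ij[1]], rs[ij[2]]))
      cf[ij[1], ] <- -1; cf[, ij[2]] <- -1
    }
    acc <- hits / length(estimated)
  }
  list(accuracy = acc, mapping = mapping)
}

# All permutations of 1..n as a matrix (n! rows); n is expected small.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))))
}
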