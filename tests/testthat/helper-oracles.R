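# Independent oracles used across test files. These implementations share no
# code with the package paths they check.

# --- adjusted mutual information, by exhaustive permutation enumeration ----

# Plain mutual information from a contingency table (natural log).
mi_plain <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  mi
}

entropy_plain <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))))
}

# AMI with the chance term obtained by averaging MI over every permutation
# of one labeling (the exact permutation-model expectation for small n).
ami_bruteforce <- function(a, b) {
  n <- length(a)
  h <- (entropy_plain(a) + entropy_plain(b)) / 2
  if (h == 0) return(1)
  P <- perms_of(n)
  emi <- mean(vapply(seq_len(nrow(P)), function(r) mi_plain(a, b[P[r, ]]),
                     numeric(1)))
  denom <- h - emi
  if (abs(denom) < 1e-15) return(0)
  unname((mi_plain(a, b) - emi) / denom)
}

# --- Cliff's delta by brute-force pair enumeration ------------------------

cliffs_delta_bruteforce <- function(a, b) {
  cmp <- outer(a, b, function(x, y) sign(x - y))
  (sum(cmp == 1) - sum(cmp == -1)) / (length(a) * length(b))
}

# --- beta regression by direct maximum likelihood -------------------------

# Logit-link beta regression fitted with optim on the joint (coef, log phi)
# likelihood; X is the model matrix.
beta_mle_oracle <- function(X, y) {
  nll <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    mu <- plogis(as.numeric(X %*% beta))
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  init <- c(qlogis(mean(y)), rep(0, ncol(X) - 1), log(5))
  fit <- optim(init, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(coef = fit$par[-length(fit$par)], phi = exp(fit$par[length(fit$par)]),
       convergence = fit$convergence)
}

# --- simple 3-D rotation for constructing switching-VAR fixtures ----------

rot3 <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Switching vector autoregression with known per-state parameters.
make_switching_var <- function(T_n, A_list, drive_list, dwell = 60,
                               noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  K <- length(A_list)
  states <- integer(0)
  cur <- sample.int(K, 1)
  while (length(states) < T_n) {
    len <- rgeom(1, 1 / dwell) + 1L
    states <- c(states, rep(cur, len))
    cur <- if (K > 1) sample(setdiff(seq_len(K), cur), 1) else cur
  }
  states <- states[seq_len(T_n)]
  z <- matrix(0, T_n, 3)
  for (t in 2:T_n) {
    k <- states[t]
    z[t, ] <- as.numeric(A_list[[k]] %*% z[t - 1, ]) + drive_list[[k]] +
      rnorm(3, sd = noise_sd)
  }
  list(latents = z, states = states)
}
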