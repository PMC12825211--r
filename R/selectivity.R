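# The entropy-based selectivity score and the group comparison statistics:
# bootstrap resampling, beta regression with a logit link, Mann-Whitney U,
# Cohen's d, and Cliff's delta.

#' Syllable-by-configuration table
#'
#' Counts each syllable's frames within every retained configuration's ON
#' epochs and normalizes to per-configuration proportions `p_ij`. The
#' syllable universe size `N` is the number of distinct syllables observed
#' across all retained configurations of the trial. `unit = "bouts"` counts
#' syllable occurrences (bouts starting inside the ON span) instead of
#' frames.
#'
#' @param seq A `syllable_sequence` (or plain integer state vector).
#' @param epochs An [epoch_table()], preferably with the `retained` flag
#'   from [movement_gate()] (missing flag retains everything).
#' @param unit `"frames"` (default) or `"bouts"`.
#' @return List of class `selectivity_table`: `counts` (configuration x
#'   syllable), `p` (row-normalized), `n_syllables` (N), `labels`,
#'   `excluded` (labels dropped by the gate or empty).
#' @export
syllable_config_table <- function(seq, epochs, unit = c("frames", "bouts")) {
  unit <- match.arg(unit)
  states <- if (inherits(seq, "syllable_sequence")) seq$states else
    as.integer(seq)
  retained <- if ("retained" %in% names(epochs)) epochs$retained else
    rep(TRUE, nrow(epochs))
  excluded <- epochs$label[!retained]
  rows <- list()
  for (i in which(retained)) {
    idx <- seq.int(epochs$on_start[i] + 1L, epochs$on_end[i])
    idx <- idx[idx <= length(states)]
    if (!length(idx)) {
      excluded <- c(excluded, epochs$label[i])
      message("configuration ", epochs$label[i],
              " has no ON frames after gating; excluded")
      next
    }
    s_on <- if (unit == "frames") states[idx] else {
      r <- rle(states[idx]); r$values
    }
    rows[[as.character(epochs$label[i])]] <- table(s_on)
  }
  if (!length(rows)) stop("no retained configuration with ON frames")
  sylls <- sort(unique(as.integer(unlist(lapply(rows, names)))))
  counts <- matrix(0L, length(rows), length(sylls),
                   dimnames = list(names(rows), sylls))
  for (lab in names(rows))
    counts[lab, names(rows[[lab]])] <- as.integer(rows[[lab]])
  structure(list(counts = counts, p = counts / rowSums(counts),
                 n_syllables = length(sylls),
                 labels = as.integer(names(rows)),
                 excluded = excluded),
            class = "selectivity_table")
}

#' Entropy-based selectivity score per configuration
#'
#' For configuration i with syllable proportions `p_ij`, the Shannon entropy
#' is `H_i = -sum_j p_ij * log(p_ij)` (natural log, with `0 log 0 = 0`) and
#' the score is `1 - H_i / log(N)`, where N is the trial's total number of
#' distinct syllables. A configuration evoking a single syllable scores 1; a
#' uniform spread over all N syllables scores 0. The score is invariant to
#' the logarithm base. With `N = 1` the score is defined as 1 (zero
#' uncertainty) with a warning.
#'
#' @param table A `selectivity_table` from [syllable_config_table()].
#' @return Data frame with `label`, `entropy` (nats), `score`.
#' @export
selectivity_score <- function(table) {
  stopifnot(inherits(table, "selectivity_table"))
  H <- apply(table$p, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  N <- table$n_syllables
  if (N == 1) {
    warning("a single syllable across all configurations; ",
            "score defined as 1")
    score <- rep(1, length(H))
  } else {
    score <- 1 - H / log(N)
  }
  data.frame(label = table$labels, entropy = unname(H),
             score = unname(score))
}

#' Bootstrap comparison of group mean selectivity
#'
#' For each group, draws `B` resamples of size `m` with replacement, and
#' reports the mean of the resample means with its 2.5/97.5 percentile
#' interval, plus a flag for CI overlap between the first two groups.
#'
#' @param scores Numeric vector of selectivity scores.
#' @param group Group labels (e.g. stimulation type), same length.
#' @param m Resample size (default 100).
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `summary` (data frame: group, n, boot_mean, ci_lo,
#'   ci_hi), `boot_means` (B x groups matrix), `ci_overlap`.
#' @export
bootstrap_means <- function(scores, group, m = 100, B = 1000, seed = 1) {
  if (m < 1 || B < 1) stop("m and B must be at least 1")
  group <- as.factor(group)
  if (any(tabulate(group) == 0)) stop("every group must be non-empty")
  set.seed(seed)
  gl <- levels(group)
  boot <- sapply(gl, function(g) {
    x <- scores[group == g]
    colMeans(matrix(x[sample.int(length(x), m * B, replace = TRUE)], m, B))
  })
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975))
  summary <- data.frame(group = gl, n = as.integer(table(group)[gl]),
                        boot_mean = colMeans(boot),
                        ci_lo = ci[1, ], ci_hi = ci[2, ],
                        row.names = NULL)
  overlap <- if (length(gl) >= 2)
    summary$ci_lo[1] <= summary$ci_hi[2] &&
      summary$ci_lo[2] <= summary$ci_hi[1] else NA
  list(summary = summary, boot_means = boot, ci_overlap = overlap)
}

#' Beta regression of selectivity scores
#'
#' Maximum-likelihood beta regression with a logit mean link, for outcomes
#' bounded in \[0, 1\]. Scores are first compressed away from the boundary
#' with `y' = (y * (n - 1) + 0.5) / n` (the standard interval-compression
#' transform), then fit by maximum likelihood with an established
#' beta-family routine. Typical usage models the score on stimulation type,
#' electrode configuration, and subject:
#' `score ~ stim_type + config + subject`.
#'
#' @param formula Model formula; the response must be the score.
#' @param data Data frame with the response in \[0, 1\] and predictors.
#' @return List of class `beta_regression`: `coefficients` (data frame with
#'   estimate, std_error, z, p for every mean-model coefficient), `phi`
#'   (precision), `fit` (the underlying model object), `n`.
#' @export
beta_regression <- function(formula, data) {
  resp <- all.vars(formula)[1]
  y <- data[[resp]]
  if (any(y < 0 | y > 1)) stop("scores must lie in [0, 1]")
  n <- length(y)
  data[[resp]] <- (y * (n - 1) + 0.5) / n
  fit <- glmmTMB::glmmTMB(formula, data = data,
                          family = glmmTMB::beta_family(link = "logit"))
  if (!isTRUE(fit$fit$convergence == 0) || !isTRUE(fit$sdr$pdHess))
    stop("beta regression did not converge; check for separation ",
         "or degenerate predictors")
  ct <- summary(fit)$coefficients$cond
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      std_error = ct[, 2], z = ct[, 3], p = ct[, 4],
                      row.names = NULL)
  structure(list(coefficients = coefs, phi = stats::sigma(fit),
                 fit = fit, n = n),
            class = "beta_regression")
}

#' Nonparametric group comparison: U test and effect sizes
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction), Cohen's d with the pooled-SD convention, and Cliff's delta
#' `(#(a > b) - #(a < b)) / (n_a * n_b)` computed via the rank-based fast
#' formula.
#'
#' @param a,b Numeric score vectors (each of length >= 2).
#' @return List with `U`, `p`, `cohen_d`, `cliffs_delta`.
#' @export
nonparametric_effects <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  list(U = unname(wt$statistic), p = wt$p.value, cohen_d = d,
       cliffs_delta = cliffs_delta(a, b))
}

#' Cliff's delta
#'
#' Rank-based computation: with `U = #(a > b) + 0.5 * #(a = b)` obtained
#' from the joint ranking, `delta = (2U - n_a n_b) / (n_a n_b)`, i.e. the
#' probability that a value from `a` exceeds one from `b` minus the
#' reverse.
#'
#' @param a,b Numeric vectors.
#' @return Delta in \[-1, 1\].
#' @export
cliffs_delta <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  (2 * U - na * nb) / (na * nb)
}
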