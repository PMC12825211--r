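# Adjusted mutual information between two labelings, with the chance
# correction computed analytically under the hypergeometric (fixed-marginal
# permutation) model. Natural logarithms throughout; AMI itself is
# base-invariant.

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement: the expected MI of two
#' labelings with the observed class sizes under random permutation is
#' subtracted and the result is normalized by the arithmetic mean of the two
#' label entropies minus that expectation. Identical partitions (up to label
#' renaming) score 1; independent labelings score approximately 0.
#'
#' Positions where either labeling equals `-1` (the density-clustering noise
#' label) are excluded before scoring. When both labelings consist of a
#' single class the score is defined as 1 (perfect, trivially certain
#' agreement).
#'
#' @param labels_a,labels_b Integer (or factor) label vectors of equal
#'   length.
#' @param exclude_noise Drop positions labeled `-1` in either vector
#'   (default TRUE).
#' @return AMI score (about 0 to 1).
#' @export
ami <- function(labels_a, labels_b, exclude_noise = TRUE) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  a <- as.integer(as.factor(labels_a))
  b <- as.integer(as.factor(labels_b))
  if (exclude_noise) {
    keep <- labels_a != -1 & labels_b != -1
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n < 2) stop("need at least 2 non-noise positions")
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  h_a <- label_entropy(ai, n)
  h_b <- label_entropy(bj, n)
  if (h_a == 0 && h_b == 0) return(1)
  mi <- mutual_information(tab, n)
  emi <- expected_mi(ai, bj, n)
  hmean <- (h_a + h_b) / 2
  denom <- hmean - emi
  if (abs(denom) < 1e-15) return(0)
  unname((mi - emi) / denom)
}

label_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(tab, n) {
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  mi
}

# Expected MI under the fixed-marginal hypergeometric model: for every cell,
# sum over all feasible cell counts weighted by their hypergeometric
# probability.
expected_mi <- function(ai, bj, n) {
  lg <- lgamma(seq_len(n + 1))   # lgamma(k+1) = log(k!)
  lf <- function(k) lg[k + 1]
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      a <- ai[i]; b <- bj[j]
      lo <- max(1, a + b - n); hi <- min(a, b)
      if (lo > hi) next
      for (nij in lo:hi) {
        lprob <- lf(a) + lf(b) + lf(n - a) + lf(n - b) -
          (lf(n) + lf(nij) + lf(a - nij) + lf(b - nij) + lf(n - a - b + nij))
        emi <- emi + (nij / n) * log(n * nij / (a * b)) * exp(lprob)
      }
    }
  }
  emi
}
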