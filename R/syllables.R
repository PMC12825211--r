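# Per-syllable kinematic summaries and cosine-metric similarity dendrograms.

#' Per-syllable trajectory statistics
#'
#' For each syllable: the mean keypoint coordinate vector (x and y of every
#' keypoint, averaged over a fixed window from each bout onset, truncated at
#' bout ends), the mean frame-to-frame keypoint speed (px/s), and frame/bout
#' counts. Syllables occupying less than `prune` of all frames are excluded
#' from the report (noted via a message).
#'
#' @param seq A `syllable_sequence` (see [syllable_sequence()]).
#' @param series The [keypoint_series()] the syllables were decoded from.
#' @param window Averaging window from bout onset, frames (default 30,
#'   i.e. 0.5 s at 60 fps).
#' @param prune Minimum frame fraction for a syllable to be reported
#'   (default 0.005).
#' @return List of class `syllable_stats`: `table` (data frame with
#'   syllable, n_frames, n_bouts, mean_speed), `vectors` (syllable x 2K mean
#'   coordinate matrix), `offset_vectors` (`vectors` minus the grand mean
#'   pose — the movement component).
#' @export
syllable_statistics <- function(seq, series, window = 30, prune = 0.005) {
  stopifnot(inherits(seq, "syllable_sequence"),
            inherits(series, "keypoint_series"))
  T_n <- nrow(series$x)
  if (length(seq$states) != T_n)
    stop("syllable sequence and series lengths differ")
  coords <- cbind(series$x, series$y)
  colnames(coords) <- c(paste0(series$bodyparts, "_x"),
                        paste0(series$bodyparts, "_y"))
  dx <- diff(series$x); dy <- diff(series$y)
  speed <- c(0, rowMeans(sqrt(dx^2 + dy^2))) * series$fps

  ids <- sort(unique(seq$states))
  keep <- ids[sapply(ids, function(s) sum(seq$states == s)) >= prune * T_n]
  dropped <- setdiff(ids, keep)
  if (length(dropped))
    message("excluding ", length(dropped),
            " syllable(s) below the usage threshold: ",
            paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no syllable exceeds the usage threshold")

  vecs <- matrix(NA_real_, length(keep), ncol(coords),
                 dimnames = list(keep, colnames(coords)))
  tab <- data.frame(syllable = keep, n_frames = NA_integer_,
                    n_bouts = NA_integer_, mean_speed = NA_real_)
  for (r in seq_along(keep)) {
    s <- keep[r]
    bouts <- which(seq$bout_states == s)
    win_idx <- unlist(lapply(bouts, function(b) {
      len <- min(window, seq$durations[b])
      seq$onsets[b] + seq_len(len)   # onsets are 0-based
    }))
    vecs[r, ] <- colMeans(coords[win_idx, , drop = FALSE])
    frames <- which(seq$states == s)
    tab$n_frames[r] <- length(frames)
    tab$n_bouts[r] <- length(bouts)
    tab$mean_speed[r] <- mean(speed[frames])
  }
  structure(list(table = tab, vectors = vecs,
                 offset_vectors = sweep(vecs, 2, colMeans(coords))),
            class = "syllable_stats")
}

#' Pairwise cosine distances
#'
#' `1 - (u . v) / (|u| |v|)` for every row pair; zero-norm rows are an
#' error (the cosine is undefined).
#'
#' @param vectors Numeric matrix, one vector per row.
#' @return A `dist` object.
#' @export
cosine_distances <- function(vectors) {
  vectors <- as.matrix(vectors)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("cosine distance undefined for zero-norm vector(s): row ",
         paste(which(norms == 0), collapse = ", "))
  sim <- tcrossprod(vectors / norms)
  sim[sim > 1] <- 1; sim[sim < -1] <- -1
  as.dist(1 - sim)
}

#' Cosine-metric syllable dendrogram
#'
#' Average-linkage agglomerative clustering of syllable vectors under the
#' cosine distance; taller merges indicate more distinct syllables.
#'
#' @param stats A `syllable_stats` object or a numeric matrix of syllable
#'   vectors (one per row).
#' @param use For `syllable_stats` input: `"offset_vectors"` (default;
#'   movement component) or `"vectors"` (raw mean pose).
#' @return List with `hclust` (the linkage tree), `dist` (pairwise cosine
#'   distances), `mean_distance`.
#' @export
syllable_dendrogram <- function(stats, use = c("offset_vectors", "vectors")) {
  use <- match.arg(use)
  vectors <- if (inherits(stats, "syllable_stats")) stats[[use]] else
    as.matrix(stats)
  if (nrow(vectors) < 2)
    stop("need at least 2 syllables for a dendrogram")
  d <- cosine_distances(vectors)
  list(hclust = hclust(d, method = "average"), dist = d,
       mean_distance = mean(d))
}
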