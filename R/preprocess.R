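# From raw keypoint tables to the standardized 10-D position matrix:
# likelihood filtering, median imputation, Euclidean flattening, per-column
# z-scoring, velocity-based movement gating, and tracking-error evaluation.

#' Mask low-confidence keypoint samples
#'
#' Cells with tracking likelihood strictly below `threshold` are masked
#' (set to `NA` in x and y); everything else is untouched. The number of
#' masked cells is attached as attribute `n_masked`. A keypoint whose cells
#' are all masked triggers a warning naming it.
#'
#' @param series A [keypoint_series()].
#' @param threshold Likelihood threshold in \[0, 1\] (default 0.5).
#' @return The series with masked cells and attribute `n_masked`.
#' @export
filter_low_likelihood <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "keypoint_series"),
            threshold >= 0, threshold <= 1)
  mask <- series$likelihood < threshold
  series$x[mask] <- NA_real_
  series$y[mask] <- NA_real_
  all_masked <- colSums(!mask) == 0
  if (any(all_masked))
    warning("all frames masked for keypoint(s): ",
            paste(series$bodyparts[all_masked], collapse = ", "))
  attr(series, "n_masked") <- sum(mask)
  series
}

#' Impute masked keypoint samples by the per-keypoint median
#'
#' Each masked cell's x and y are replaced by the median of that keypoint's
#' unmasked x and y positions. By default the median is taken over the whole
#' trial; `window` selects a centred rolling window (in frames) instead,
#' falling back to the whole-trial median where a window holds no unmasked
#' sample.
#'
#' @param series A series with masked (`NA`) cells, as produced by
#'   [filter_low_likelihood()].
#' @param window Optional odd window length in frames; `NULL` (default) uses
#'   the whole trial.
#' @return A complete [keypoint_series()].
#' @export
impute_median <- function(series, window = NULL) {
  stopifnot(inherits(series, "keypoint_series"))
  for (k in seq_along(series$bodyparts)) {
    for (coord in c("x", "y")) {
      v <- series[[coord]][, k]
      na <- is.na(v)
      if (!any(na)) next
      if (all(na))
        stop("keypoint '", series$bodyparts[k],
             "' is fully masked; cannot impute")
      global_med <- median(v[!na])
      if (is.null(window)) {
        v[na] <- global_med
      } else {
        half <- floor(window / 2)
        for (t in which(na)) {
          lo <- max(1, t - half); hi <- min(length(v), t + half)
          w <- v[lo:hi]
          v[t] <- if (all(is.na(w))) global_med else median(w, na.rm = TRUE)
        }
      }
      series[[coord]][, k] <- v
    }
  }
  series
}

#' Flatten x, y coordinates to per-keypoint planar magnitudes
#'
#' Collapses each keypoint's (x, y) to a single Euclidean magnitude
#' `sqrt((x - ox)^2 + (y - oy)^2)`, yielding the T x K position matrix. The
#' origin is the image origin (0, 0) by default, or the hip keypoint's
#' per-frame position (`"hip_anchored"`), which removes whole-limb
#' translation.
#'
#' @param series A complete [keypoint_series()].
#' @param origin `"image_origin"` or `"hip_anchored"`.
#' @return T x K numeric matrix with keypoint column names.
#' @export
flatten_euclidean <- function(series,
                              origin = c("image_origin", "hip_anchored")) {
  stopifnot(inherits(series, "keypoint_series"))
  origin <- match.arg(origin)
  if (anyNA(series$x) || anyNA(series$y))
    stop("series has masked cells; impute before flattening")
  if (origin == "image_origin") {
    ox <- 0; oy <- 0
  } else {
    hip <- which(series$bodyparts == "hip")
    if (!length(hip)) stop("hip keypoint required for hip_anchored origin")
    ox <- series$x[, hip]; oy <- series$y[, hip]
  }
  sqrt((series$x - ox)^2 + (series$y - oy)^2)
}

#' Z-score position-matrix columns
#'
#' Per-column standardization using the population SD convention
#' (denominator T). Column means and SDs are stored as attributes `center`
#' and `scale` so [unstandardize()] is an exact inverse.
#'
#' @param mat T x K position matrix.
#' @return Standardized matrix with `center`/`scale` attributes.
#' @export
standardize <- function(mat) {
  mat <- as.matrix(mat)
  ctr <- colMeans(mat)
  scl <- sqrt(colMeans(sweep(mat, 2, ctr)^2))
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(mat)[zero], collapse = ", "))
  out <- sweep(sweep(mat, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert [standardize()]
#' @param mat A matrix produced by [standardize()].
#' @return The original-scale matrix.
#' @export
unstandardize <- function(mat) {
  ctr <- attr(mat, "center"); scl <- attr(mat, "scale")
  if (is.null(ctr) || is.null(scl)) stop("matrix lacks center/scale attributes")
  out <- sweep(sweep(mat, 2, scl, "*"), 2, ctr, "+")
  attributes(out)[c("center", "scale")] <- NULL
  out
}

#' Per-frame limb speed
#'
#' Frame-to-frame Euclidean displacement of the (unstandardized) flattened
#' position vector, scaled by the frame rate (px/s). The first frame's speed
#' repeats the second's so the vector has one entry per frame.
#'
#' @param values T x K unstandardized position matrix.
#' @param fps Frame rate.
#' @return Numeric vector of length T.
#' @export
frame_speed <- function(values, fps) {
  d <- diff(values)
  sp <- sqrt(rowSums(d^2)) * fps
  c(sp[1], sp)
}

#' Gate configurations by evoked movement
#'
#' A configuration is retained if and only if the peak of its smoothed
#' ON-epoch speed exceeds `baseline_mean + k_sd * baseline_SD`, where the
#' baseline statistics come from all OFF/rest frames. Configurations that do
#' not move the limb above this velocity threshold are flagged for removal
#' from the selectivity analysis.
#'
#' @param values T x K unstandardized position matrix.
#' @param epochs An [epoch_table()].
#' @param fps Frame rate.
#' @param k_sd Threshold multiplier (baseline mean + `k_sd` SD; default 3).
#' @param smooth_s Rolling-mean window for speed smoothing, seconds.
#' @return The epoch table with logical column `retained` and numeric
#'   columns `peak_speed` and `threshold`.
#' @export
movement_gate <- function(values, epochs, fps, k_sd = 3, smooth_s = 0.25) {
  sp <- frame_speed(values, fps)
  w <- max(1L, round(smooth_s * fps))
  sp_smooth <- as.numeric(stats::filter(sp, rep(1 / w, w), sides = 2))
  sp_smooth[is.na(sp_smooth)] <- sp[is.na(sp_smooth)]
  off_idx <- unlist(lapply(seq_len(nrow(epochs)), function(i)
    if (epochs$off_end[i] > epochs$off_start[i])
      seq.int(epochs$off_start[i] + 1L, epochs$off_end[i]) else integer(0)))
  off_idx <- off_idx[off_idx <= length(sp)]
  if (!length(off_idx)) stop("no OFF frames available to estimate baseline")
  base_mean <- mean(sp[off_idx])
  base_sd <- sd(sp[off_idx])
  threshold <- base_mean + k_sd * base_sd
  peak <- vapply(seq_len(nrow(epochs)), function(i) {
    idx <- seq.int(epochs$on_start[i] + 1L, epochs$on_end[i])
    max(sp_smooth[idx])
  }, numeric(1))
  epochs$peak_speed <- peak
  epochs$threshold <- threshold
  epochs$retained <- peak > threshold
  epochs
}

#' Evaluate tracking error against labeled frames
#'
#' Per-keypoint median Euclidean distance between predicted and manually
#' labeled positions, plus the pooled overall median, converted to mm.
#'
#' @param predicted,labeled [keypoint_series()] objects over the same frames
#'   and keypoints.
#' @param mm_per_px Pixel-to-mm scale (> 0).
#' @return List with `per_keypoint_mm` (named vector) and `overall_mm`.
#' @export
evaluate_tracking_error <- function(predicted, labeled, mm_per_px) {
  stopifnot(mm_per_px > 0)
  if (!identical(predicted$bodyparts, labeled$bodyparts))
    stop("keypoint-name mismatch between predicted and labeled series")
  if (nrow(predicted$x) != nrow(labeled$x))
    stop("frame-count mismatch between predicted and labeled series")
  err <- sqrt((predicted$x - labeled$x)^2 +
              (predicted$y - labeled$y)^2) * mm_per_px
  list(per_keypoint_mm = apply(err, 2, median),
       overall_mm = median(err))
}

#' Full preprocessing pipeline for one trial
#'
#' Likelihood filter -> median imputation -> Euclidean flattening ->
#' z-scoring, plus the velocity-based movement gate on the unstandardized
#' values.
#'
#' @param series A [keypoint_series()].
#' @param epochs An [epoch_table()].
#' @param likelihood_threshold Passed to [filter_low_likelihood()].
#' @param origin Passed to [flatten_euclidean()].
#' @param impute_window Passed to [impute_median()].
#' @param k_sd Passed to [movement_gate()].
#' @return List with `values` (standardized T x K matrix), `raw_values`
#'   (unstandardized), `epochs` (gated), `labels` (per-frame configuration
#'   tag, `NA` during rest), `n_masked`.
#' @export
preprocess_trial <- function(series, epochs, likelihood_threshold = 0.5,
                             origin = "image_origin", impute_window = NULL,
                             k_sd = 3) {
  filt <- filter_low_likelihood(series, likelihood_threshold)
  n_masked <- attr(filt, "n_masked")
  complete <- impute_median(filt, window = impute_window)
  raw <- flatten_euclidean(complete, origin = origin)
  gated <- movement_gate(raw, epochs, fps = series$fps, k_sd = k_sd)
  list(values = standardize(raw), raw_values = raw, epochs = gated,
       labels = frame_labels(epochs, nrow(raw)), n_masked = n_masked)
}
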