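# Epoch tables and the two external text formats: pose-estimation CSV
# (three header rows: scorer / bodyparts / coords) and the timestamped
# configuration sweep log.

#' Construct / validate a stimulation epoch table
#'
#' One row per configuration epoch. Frame spans are 0-based and half-open:
#' ON covers `[on_start, on_end)`, the following rest period
#' `[off_start, off_end)`.
#'
#' @param df Data frame with columns `label`, `mode`, `on_start`, `on_end`,
#'   `off_start`, `off_end`, `subject_id` and optionally `channels`.
#' @return The validated data frame with class `epoch_table`.
#' @export
epoch_table <- function(df) {
  req <- c("label", "mode", "on_start", "on_end", "off_start", "off_end",
           "subject_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("epoch table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"channels" %in% names(df)) df$channels <- NA_character_
  if (any(df$on_end <= df$on_start) || any(df$off_end < df$off_start))
    stop("epoch table validation: empty or negative spans")
  if (is.unsorted(df$on_start, strictly = TRUE))
    stop("epoch table validation: epochs out of order")
  ends <- df$off_end[-nrow(df)]
  if (nrow(df) > 1 && any(df$on_start[-1] < ends))
    stop("epoch table validation: overlapping epochs")
  if (any(df$off_start != df$on_end))
    stop("epoch table validation: rest span must start at on_end")
  class(df) <- c("epoch_table", "data.frame")
  df
}

#' Per-frame configuration tag
#'
#' Expands an epoch table to a per-frame label vector: the configuration
#' label during its ON span, `NA` during OFF/rest frames.
#'
#' @param epochs An [epoch_table()].
#' @param n_frames Total number of frames.
#' @return Integer vector of length `n_frames`.
#' @export
frame_labels <- function(epochs, n_frames) {
  out <- rep(NA_integer_, n_frames)
  for (i in seq_len(nrow(epochs))) {
    idx <- seq.int(epochs$on_start[i] + 1L, epochs$on_end[i])
    out[idx] <- epochs$label[i]
  }
  out
}

#' Write a keypoint series as a pose-estimation CSV
#'
#' The dialect has three header rows — scorer, bodyparts, coords — with an
#' (x, y, likelihood) column triplet per keypoint and a leading frame-index
#' column, followed by one row per frame.
#'
#' @param series A [keypoint_series()].
#' @param path Output file path.
#' @param scorer Scorer/model name written into the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(series, path, scorer = "stimselect") {
  stopifnot(inherits(series, "keypoint_series"))
  K <- length(series$bodyparts)
  header1 <- c("scorer", rep(scorer, 3 * K))
  header2 <- c("bodyparts", rep(series$bodyparts, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), K))
  T_n <- nrow(series$x)
  data <- matrix(NA_real_, T_n, 3 * K)
  data[, seq(1, 3 * K, 3)] <- series$x
  data[, seq(2, 3 * K, 3)] <- series$y
  data[, seq(3, 3 * K, 3)] <- series$likelihood
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  body <- cbind(format(seq_len(T_n) - 1L, trim = TRUE, scientific = FALSE),
                formatC(data, format = "g", digits = 15))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a pose-estimation CSV
#'
#' Parses the three-header-row dialect written by [write_dlc_csv()] (and by
#' standard pose-estimation exports). Malformed header rows raise an error
#' naming the offending row.
#'
#' @param path Input file path.
#' @param fps Frame rate to attach to the series (not stored in the format).
#' @return A [keypoint_series()].
#' @export
read_dlc_csv <- function(path, fps = 60) {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3)
    stop("malformed pose CSV: fewer than 3 header rows")
  h1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (tolower(h1[1]) != "scorer")
    stop("malformed pose CSV header row 1: expected leading 'scorer' cell")
  if (tolower(h2[1]) != "bodyparts")
    stop("malformed pose CSV header row 2: expected leading 'bodyparts' cell")
  if (tolower(h3[1]) != "coords" ||
      !all(h3[-1] == rep(c("x", "y", "likelihood"),
                         length.out = length(h3) - 1)))
    stop("malformed pose CSV header row 3: expected repeating x,y,likelihood")
  bodyparts <- unique(h2[-1])
  if ((length(h2) - 1) != 3 * length(bodyparts))
    stop("malformed pose CSV header row 2: bodyparts not in triplets")
  dat <- read.csv(path, skip = 3, header = FALSE)
  vals <- as.matrix(dat[, -1, drop = FALSE])
  K <- length(bodyparts)
  keypoint_series(x = vals[, seq(1, 3 * K, 3), drop = FALSE],
                  y = vals[, seq(2, 3 * K, 3), drop = FALSE],
                  likelihood = vals[, seq(3, 3 * K, 3), drop = FALSE],
                  bodyparts = bodyparts, fps = fps)
}

#' Write a timestamped configuration sweep log
#'
#' One line per configuration change: ISO-8601 timestamp (derived from the
#' ON-start frame and `fps`, relative to `t0`), stimulation mode,
#' configuration label, active channels, frame spans and subject ID — the
#' structured .txt format produced by an automated multiplexer sweep.
#'
#' @param epochs An [epoch_table()], ordered by time.
#' @param path Output file path.
#' @param fps Frame rate used to convert frames to timestamps.
#' @param t0 POSIXct start time of the recording.
#' @return `path`, invisibly.
#' @export
write_sweep_log <- function(epochs, path, fps = 60,
                            t0 = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  epochs <- epoch_table(as.data.frame(epochs))  # re-validate (order, overlap)
  ts <- t0 + epochs$on_start / fps
  lines <- sprintf(
    "%s\tmode=%s\tlabel=%d\tchannels=%s\ton=%d:%d\toff=%d:%d\tsubject=%s",
    format(ts, "%Y-%m-%dT%H:%M:%OS3Z"), epochs$mode, epochs$label,
    epochs$channels, epochs$on_start, epochs$on_end,
    epochs$off_start, epochs$off_end, epochs$subject_id)
  writeLines(c("# stimselect sweep log v1", lines), path)
  invisible(path)
}

#' Read a configuration sweep log
#'
#' @param path Path to a file written by [write_sweep_log()].
#' @return An [epoch_table()].
#' @export
read_sweep_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("sweep log contains no configuration lines")
  field <- function(parts, key) {
    hit <- grep(paste0("^", key, "="), parts, value = TRUE)
    if (!length(hit)) stop("sweep log line missing field '", key, "'")
    sub(paste0("^", key, "="), "", hit[1])
  }
  rows <- lapply(strsplit(lines, "\t", fixed = TRUE), function(parts) {
    on <- as.integer(strsplit(field(parts, "on"), ":")[[1]])
    off <- as.integer(strsplit(field(parts, "off"), ":")[[1]])
    data.frame(label = as.integer(field(parts, "label")),
               mode = field(parts, "mode"),
               on_start = on[1], on_end = on[2],
               off_start = off[1], off_end = off[2],
               subject_id = field(parts, "subject"),
               channels = field(parts, "channels"),
               stringsAsFactors = FALSE)
  })
  epoch_table(do.call(rbind, rows))
}
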