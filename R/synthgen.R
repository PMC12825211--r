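# Synthetic pose-estimation trials with known configuration -> motif structure.
#
# A trial alternates stimulation-ON epochs (one electrode configuration each)
# with OFF rest epochs. During ON, a 3-D latent state follows a stable
# first-order vector-autoregression (one VAR generator per movement motif) and
# is emitted linearly as keypoint offsets around a hindlimb rest pose; during
# OFF, keypoint offsets relax exponentially back to rest. Tracking noise and
# low-likelihood dropouts emulate pose-estimation artifacts.

#' Construct a keypoint series
#'
#' @param x,y Numeric T x K matrices of pixel coordinates.
#' @param likelihood Numeric T x K matrix in \[0, 1\] (tracking confidence).
#' @param bodyparts Character vector of K keypoint names.
#' @param fps Frames per second of the source video.
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(x, y, likelihood, bodyparts = hindlimb_keypoints(),
                            fps = 60) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  stopifnot(nrow(x) >= 1, all(dim(x) == dim(y)), all(dim(x) == dim(likelihood)))
  if (ncol(x) != length(bodyparts))
    stop("number of columns must equal number of bodyparts")
  if (any(likelihood < 0 | likelihood > 1))
    stop("likelihood values must lie in [0, 1]")
  colnames(x) <- colnames(y) <- colnames(likelihood) <- bodyparts
  structure(list(x = x, y = y, likelihood = likelihood,
                 bodyparts = bodyparts, fps = fps),
            class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %d frames x %d keypoints @ %g fps\n",
              nrow(x$x), length(x$bodyparts), x$fps))
  invisible(x)
}

#' Hindlimb rest pose
#'
#' Baseline pixel coordinates for the ten keypoints arranged in a
#' hindlimb-like arc (hip proximal, toes fanned distally), in a nominal
#' 640 x 480 top-view frame.
#'
#' @return A 10 x 2 matrix (columns x, y) with keypoint row names.
#' @export
rest_pose_hindlimb <- function() {
  m <- rbind(
    hip    = c(150, 200),
    knee   = c(210, 165),
    ankle  = c(265, 205),
    heel   = c(285, 245),
    instep = c(330, 235),
    toe_1  = c(375, 200),
    toe_2  = c(385, 215),
    toe_3  = c(390, 230),
    toe_4  = c(385, 245),
    toe_5  = c(375, 260))
  colnames(m) <- c("x", "y")
  m
}

# Rotation matrix about a 3-D unit axis by angle theta (Rodrigues).
rotation3 <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Deterministic well-spread unit directions (spherical Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a movement-motif library
#'
#' Each motif is a stable order-1 vector autoregression in a 3-D latent space:
#' a damped rotation (one oscillation frequency per motif) around a motif-
#' specific attractor, with Gaussian process noise. A fixed linear map emits
#' the latent state as keypoint offsets around the rest pose.
#'
#' Two regimes are supported. In the `"selective"` regime every configuration
#' label is assigned its own motif and motif attractors are spread widely
#' (each configuration evokes a distinct movement). In the `"nonselective"`
#' regime all configurations share a small pool of `n_shared` motifs whose
#' attractors and frequencies are deliberately similar, and the generator
#' switches between them within an ON epoch — emulating paradigms whose
#' evoked movements are few, kinematically alike, and not configuration
#' specific.
#'
#' @param labels Integer vector of configuration labels the library must
#'   cover (the trial schedule).
#' @param regime `"selective"` or `"nonselective"`.
#' @param n_shared Number of shared motifs in the nonselective regime.
#' @param seed Integer seed for the library's random draws.
#' @param fps Frames per second (oscillation phase advance is per frame).
#' @param amplitude_px Pixel displacement per unit of latent state.
#' @param attractor_radius Latent-space radius of motif attractors.
#' @param osc_hz Range of motif oscillation frequencies (Hz).
#' @param ar_decay Spectral radius of each motif's AR matrix (< 1).
#' @param latent_noise_sd Process-noise SD in latent units.
#' @return An object of class `motif_library`.
#' @export
motif_library <- function(labels, regime = c("selective", "nonselective"),
                          n_shared = 3, seed = 1, fps = 60,
                          amplitude_px = 20, attractor_radius = 2.2,
                          osc_hz = c(1.5, 6), ar_decay = 0.97,
                          latent_noise_sd = 0.22) {
  regime <- match.arg(regime)
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 1, !anyDuplicated(labels), ar_decay < 1)
  set.seed(derive_seed(seed, "motif_library"))
  n_motifs <- if (regime == "selective") length(labels) else n_shared

  if (regime == "selective") {
    dirs <- fibonacci_directions(max(n_motifs, 2))[seq_len(n_motifs), , drop = FALSE]
    freqs <- seq(osc_hz[1], osc_hz[2], length.out = n_motifs)
  } else {
    # Neighbouring attractors and a narrow frequency band: similar motifs.
    base <- fibonacci_directions(2)[1, ]
    dirs <- t(vapply(seq_len(n_motifs), function(m) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      as.numeric(rotation3(ax, 0.25) %*% base)
    }, numeric(3)))
    mid <- mean(osc_hz)
    freqs <- seq(mid - 0.4, mid + 0.4, length.out = n_motifs)
  }

  motifs <- lapply(seq_len(n_motifs), function(m) {
    axis <- rnorm(3)
    A <- ar_decay * rotation3(axis, 2 * pi * freqs[m] / fps)
    attractor <- attractor_radius * dirs[m, ]
    drive <- as.numeric((diag(3) - A) %*% attractor)
    list(A = A, drive = drive, attractor = attractor,
         noise_sd = latent_noise_sd, freq_hz = freqs[m])
  })

  # Fixed emission map: orthonormal columns scaled to amplitude_px px/unit.
  W <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3))) * amplitude_px

  assignment <- if (regime == "selective") {
    setNames(lapply(seq_along(labels), identity), labels)
  } else {
    setNames(rep(list(seq_len(n_motifs)), length(labels)), labels)
  }

  structure(list(motifs = motifs, emission = W,
                 rest_pose = rest_pose_hindlimb(),
                 assignment = assignment, regime = regime, fps = fps),
            class = "motif_library")
}

#' Specify a synthetic trial
#'
#' @param n_configs Number of electrode configurations in the trial.
#' @param mode Stimulation mode: `"TIS4"` (temporal interference, 2 pairs),
#'   `"BP2"` (bipolar biphasic), `"TT3"`/`"TL3"` (transverse/longitudinal
#'   tripolar biphasic).
#' @param on_s,off_s Stimulation ON and OFF (rest) durations in seconds.
#' @param fps Video frame rate (frames/s).
#' @param dropout_rate Fraction of (frame, keypoint) cells with tracking
#'   dropouts (likelihood below 0.5 and corrupted coordinates).
#' @param noise_px Additive tracking-noise SD in pixels.
#' @param seed Integer seed; identical seeds reproduce trials bit-for-bit.
#' @param subject_id Subject identifier carried into the epoch table.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(n_configs = 8, mode = c("TIS4", "BP2", "TT3", "TL3"),
                       on_s = 5, off_s = 5, fps = 60, dropout_rate = 0.05,
                       noise_px = 1.5, seed = 1, subject_id = "S1") {
  mode <- match.arg(mode)
  stopifnot(on_s > 0, off_s > 0, dropout_rate >= 0, dropout_rate < 1,
            noise_px >= 0, n_configs >= 1)
  structure(list(n_configs = n_configs, mode = mode, on_s = on_s,
                 off_s = off_s, fps = fps, dropout_rate = dropout_rate,
                 noise_px = noise_px, seed = as.integer(seed),
                 subject_id = subject_id),
            class = "trial_spec")
}

#' Generate a synthetic stimulation trial
#'
#' Simulates a full recording: for each configuration, an ON epoch where the
#' keypoints follow the configuration's motif dynamics (with tracking noise),
#' then an OFF epoch where they relax exponentially toward the rest pose
#' (time constant `relax_tau_s`). Ground-truth motif identity is returned per
#' frame (0 during OFF).
#'
#' @param spec A [trial_spec()].
#' @param library A [motif_library()] whose assignment covers the schedule.
#' @param labels Optional integer configuration labels (defaults to the first
#'   `n_configs` labels of the library's assignment).
#' @param relax_tau_s OFF-epoch relaxation time constant (seconds).
#' @param dwell_s Mean dwell per motif when a configuration maps to several
#'   motifs (within-epoch switching), in seconds.
#' @return A list with `series` ([keypoint_series()]), `epochs` (an epoch
#'   table, see [epoch_table()]), and `states` (integer ground-truth motif ID
#'   per frame, 0 = OFF/rest).
#' @export
generate_trial <- function(spec, library, labels = NULL,
                           relax_tau_s = 0.25, dwell_s = 1) {
  stopifnot(inherits(spec, "trial_spec"), inherits(library, "motif_library"))
  if (is.null(labels))
    labels <- as.integer(names(library$assignment))[seq_len(spec$n_configs)]
  labels <- as.integer(labels)
  if (length(labels) != spec$n_configs)
    stop("need exactly n_configs labels")
  missing <- setdiff(as.character(labels), names(library$assignment))
  if (length(missing))
    stop("missing motif assignment for configuration label(s): ",
         paste(missing, collapse = ", "))

  set.seed(spec$seed)
  fps <- spec$fps
  on_f <- round(spec$on_s * fps); off_f <- round(spec$off_s * fps)
  T_total <- spec$n_configs * (on_f + off_f)
  K <- 10L
  decay <- exp(-1 / (relax_tau_s * fps))
  W <- library$emission
  rest <- library$rest_pose

  offsets <- matrix(0, T_total, 20)  # columns 1:10 x-offsets, 11:20 y-offsets
  states <- integer(T_total)
  epochs <- vector("list", spec$n_configs)

  t_cur <- 0L   # 0-based frame cursor
  last_offset <- rep(0, 20)
  for (i in seq_len(spec$n_configs)) {
    lab <- labels[i]
    motif_ids <- library$assignment[[as.character(lab)]]
    # per-frame motif schedule inside this ON epoch
    if (length(motif_ids) == 1L) {
      sched <- rep(motif_ids, on_f)
    } else {
      sched <- integer(0)
      cur <- sample(motif_ids, 1)
      while (length(sched) < on_f) {
        len <- rgeom(1, 1 / (dwell_s * fps)) + 1L
        sched <- c(sched, rep(cur, len))
        cur <- sample(setdiff(motif_ids, cur), 1)
      }
      sched <- sched[seq_len(on_f)]
    }
    z <- rep(0, 3)
    for (f in seq_len(on_f)) {
      m <- library$motifs[[sched[f]]]
      z <- as.numeric(m$A %*% z) + m$drive + rnorm(3, sd = m$noise_sd)
      offsets[t_cur + f, ] <- as.numeric(W %*% z)
      states[t_cur + f] <- sched[f]
    }
    last_offset <- offsets[t_cur + on_f, ]
    # OFF epoch: exponential relaxation toward rest
    for (f in seq_len(off_f)) {
      last_offset <- last_offset * decay
      offsets[t_cur + on_f + f, ] <- last_offset
    }
    epochs[[i]] <- data.frame(
      label = lab, mode = spec$mode,
      on_start = t_cur, on_end = t_cur + on_f,
      off_start = t_cur + on_f, off_end = t_cur + on_f + off_f,
      subject_id = spec$subject_id, stringsAsFactors = FALSE)
    t_cur <- t_cur + on_f + off_f
  }
  epochs <- do.call(rbind, epochs)
  epochs$channels <- vapply(epochs$label, function(l)
    paste(config_channels(l, spec$mode), collapse = ","), character(1))
  epochs <- epoch_table(epochs)

  x <- matrix(rest[, "x"], T_total, K, byrow = TRUE) + offsets[, 1:10]
  y <- matrix(rest[, "y"], T_total, K, byrow = TRUE) + offsets[, 11:20]
  if (spec$noise_px > 0) {
    x <- x + matrix(rnorm(T_total * K, sd = spec$noise_px), T_total, K)
    y <- y + matrix(rnorm(T_total * K, sd = spec$noise_px), T_total, K)
  }

  lik <- matrix(0.5 + 0.5 * rbeta(T_total * K, 8, 1), T_total, K)
  if (spec$dropout_rate > 0) {
    drop <- matrix(runif(T_total * K) < spec$dropout_rate, T_total, K)
    n_drop <- sum(drop)
    if (n_drop > 0) {
      lik[drop] <- runif(n_drop, 0, 0.5 - 1e-9)
      jump <- 20 * spec$noise_px
      x[drop] <- x[drop] + runif(n_drop, -jump, jump)
      y[drop] <- y[drop] + runif(n_drop, -jump, jump)
    }
  }

  list(series = keypoint_series(x, y, lik, fps = fps),
       epochs = epochs, states = states)
}
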