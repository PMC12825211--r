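# The 64-channel nerve-cuff configuration space and stimulation waveforms.
#
# Channels are addressed on a logical 8 x 8 grid (channel = 8*(row-1)+col),
# consistent with the 8*(A-1)+B labeling stride. Physical pitches of the cuff
# (0.4 mm column-wise, 1.2 mm row-wise, 0.6 mm mid-column gap) are carried as
# metadata only.

#' Describe the 64-channel cuff grid
#'
#' @param rows,cols Logical grid dimensions (rows * cols must be 64).
#' @param pitch_col_mm,pitch_row_mm,mid_gap_mm Physical electrode pitches
#'   (metadata).
#' @param faulty Integer channel indices to exclude from sweeps.
#' @return An object of class `cuff_grid`.
#' @export
cuff_grid <- function(rows = 8, cols = 8, pitch_col_mm = 0.4,
                      pitch_row_mm = 1.2, mid_gap_mm = 0.6,
                      faulty = integer(0)) {
  if (rows * cols != 64) stop("cuff grid must address 64 channels")
  faulty <- as.integer(faulty)
  if (length(faulty) && (any(faulty < 1) || any(faulty > 64)))
    stop("faulty channels must be in 1..64")
  structure(list(rows = rows, cols = cols, pitch_col_mm = pitch_col_mm,
                 pitch_row_mm = pitch_row_mm, mid_gap_mm = mid_gap_mm,
                 faulty = faulty),
            class = "cuff_grid")
}

grid_channel <- function(row, col, cols = 8) (row - 1L) * cols + col

#' Temporal-interference configuration label
#'
#' Label for a two-pair interference configuration from the 1-based positions
#' of Pair A and Pair B: `8 * (A - 1) + B`.
#'
#' @param pair_a,pair_b 1-based pair positions.
#' @return Integer label (e.g. A = 2, B = 3 gives 11).
#' @export
config_label <- function(pair_a, pair_b) {
  if (any(pair_a < 1) || any(pair_b < 1))
    stop("pair positions must be positive (1-based)")
  as.integer(8 * (pair_a - 1) + pair_b)
}

#' Number of distinct active-channel sets for a stimulation mode
#'
#' The combinatorial size of the configuration space on the 64-channel cuff:
#' `choose(64, n_active)` with 4 active channels for temporal interference,
#' 2 for bipolar and 3 for tripolar biphasic layouts.
#'
#' @param mode One of `"TIS4"`, `"BP2"`, `"TT3"`, `"TL3"`.
#' @return Integer count.
#' @export
config_space_size <- function(mode = c("TIS4", "BP2", "TT3", "TL3")) {
  mode <- match.arg(mode)
  n_active <- c(TIS4 = 4, BP2 = 2, TT3 = 3, TL3 = 3)[[mode]]
  choose(64, n_active)
}

# Active channels for a given label under the default grid geometry.
# TIS pairs span same-row channels one electrode apart (cols 1&3 for Pair A,
# 5&7 for Pair B); non-TIS labels index the deterministic sweep order.
config_channels <- function(label, mode) {
  if (mode == "TIS4") {
    a <- (label - 1L) %/% 8L + 1L
    b <- (label - 1L) %% 8L + 1L
    c(grid_channel(a, 1L), grid_channel(a, 3L),
      grid_channel(b, 5L), grid_channel(b, 7L))
  } else {
    sweep <- enumerate_sweep(cuff_grid(), mode)
    row <- sweep[sweep$label == label, ]
    if (!nrow(row)) stop("unknown configuration label ", label,
                         " for mode ", mode)
    as.integer(strsplit(row$channels[1], ",")[[1]])
  }
}

#' Enumerate a deterministic configuration sweep
#'
#' Emits the ordered configuration list for one stimulation mode:
#' * `TIS4` — Pair A (same-row channels one electrode apart) steps through
#'   rows with a configurable skip while Pair B sweeps all rows; labels
#'   follow `8*(A-1)+B`.
#' * `BP2` — bipolar pairs one electrode apart, alternating (skip-one) along
#'   each row.
#' * `TT3` — transverse tripoles, three same-row channels each two apart,
#'   shifting right then down.
#' * `TL3` — longitudinal tripoles, three same-column channels each two rows
#'   apart, shifting down then right.
#'
#' Configurations touching a faulty channel are skipped. Non-TIS labels are
#' serial positions in the (fault-free) sweep order, so labels are stable
#' when channels are marked faulty.
#'
#' @param grid A [cuff_grid()].
#' @param mode Stimulation mode.
#' @param row_skip Row increment for the Pair A sweep (TIS only; every other
#'   row by default, mirroring sweeps that skip rows to avoid
#'   over-stimulation).
#' @return Data frame with columns `mode`, `label`, `pair_a`, `pair_b`
#'   (TIS only, else `NA`), `channels` (comma-separated).
#' @export
enumerate_sweep <- function(grid, mode = c("TIS4", "BP2", "TT3", "TL3"),
                            row_skip = 2) {
  stopifnot(inherits(grid, "cuff_grid"))
  mode <- match.arg(mode)
  rows <- grid$rows; cols <- grid$cols
  out <- list()
  if (mode == "TIS4") {
    for (a in seq(1, rows, by = row_skip)) for (b in seq_len(rows)) {
      ch <- c(grid_channel(a, 1L, cols), grid_channel(a, 3L, cols),
              grid_channel(b, 5L, cols), grid_channel(b, 7L, cols))
      out[[length(out) + 1]] <- data.frame(
        mode = mode, label = config_label(a, b), pair_a = a, pair_b = b,
        channels = paste(ch, collapse = ","), stringsAsFactors = FALSE)
    }
  } else if (mode == "BP2") {
    lab <- 0L
    for (r in seq_len(rows)) for (c in seq(1, cols - 2, by = 2)) {
      lab <- lab + 1L
      ch <- c(grid_channel(r, c, cols), grid_channel(r, c + 2L, cols))
      out[[length(out) + 1]] <- data.frame(
        mode = mode, label = lab, pair_a = NA, pair_b = NA,
        channels = paste(ch, collapse = ","), stringsAsFactors = FALSE)
    }
  } else if (mode == "TT3") {
    lab <- 0L
    for (r in seq_len(rows)) for (c in seq_len(cols - 4)) {
      lab <- lab + 1L
      ch <- grid_channel(r, c + c(0L, 2L, 4L), cols)
      out[[length(out) + 1]] <- data.frame(
        mode = mode, label = lab, pair_a = NA, pair_b = NA,
        channels = paste(ch, collapse = ","), stringsAsFactors = FALSE)
    }
  } else {
    lab <- 0L
    for (c in seq_len(cols)) for (r in seq_len(rows - 4)) {
      lab <- lab + 1L
      ch <- grid_channel(r + c(0L, 2L, 4L), c, cols)
      out[[length(out) + 1]] <- data.frame(
        mode = mode, label = lab, pair_a = NA, pair_b = NA,
        channels = paste(ch, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  sweep <- do.call(rbind, out)
  if (length(grid$faulty)) {
    keep <- vapply(strsplit(sweep$channels, ","), function(ch)
      !any(as.integer(ch) %in% grid$faulty), logical(1))
    sweep <- sweep[keep, , drop = FALSE]
    rownames(sweep) <- NULL
  }
  sweep
}

#' Synthesize a temporal-interference waveform and estimate its envelope
#'
#' Sums two sinusoidal carriers `a1*sin(2*pi*f1*t) + a2*sin(2*pi*f2*t)` and
#' estimates the low-frequency interference envelope, expected at `|f1 - f2|`,
#' from the magnitude of the analytic signal (FFT Hilbert transform): the
#' envelope's dominant spectral peak is reported to within one FFT bin
#' (`1/duration` Hz).
#'
#' @param f1,f2 Carrier frequencies (Hz); equal carriers yield a constant-
#'   amplitude beat (warning, envelope frequency 0).
#' @param a1,a2 Carrier amplitudes.
#' @param duration_s Synthesis duration (s); sets the spectral resolution.
#' @param sample_rate Samples per second (at least 10x the carriers).
#' @return List with `t`, `signal`, `envelope`, `envelope_freq_hz`,
#'   `modulation_depth`, and `bin_hz` (the spectral resolution).
#' @export
tis_envelope <- function(f1, f2, a1 = 1, a2 = 1, duration_s = 4,
                         sample_rate = 24000) {
  if (sample_rate < 10 * max(f1, f2))
    stop("sample_rate must be at least 10x the larger carrier frequency")
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  signal <- a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t)
  env <- Mod(analytic_signal(signal))
  freq_hz <- 0
  if (f1 == f2) {
    warning("equal carrier frequencies: constant-amplitude beat, ",
            "envelope frequency 0")
  } else {
    freq_hz <- dominant_frequency(env - mean(env), sample_rate)
  }
  depth <- (max(env) - min(env)) / (max(env) + min(env))
  list(t = t, signal = signal, envelope = env, envelope_freq_hz = freq_hz,
       modulation_depth = depth, bin_hz = 1 / duration_s)
}

# Analytic signal via the FFT: zero negative frequencies, double positive.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

dominant_frequency <- function(x, sample_rate) {
  n <- length(x)
  spec <- Mod(fft(x))[seq_len(floor(n / 2))]
  (which.max(spec) - 1) * sample_rate / n
}

#' Describe a stimulation waveform
#'
#' @param kind `"biphasic_pulse_train"` or `"tis_sine_pair"`.
#' @param amplitude_uA Current amplitude (biphasic) or peak (sinusoid), uA.
#' @param phase_width_us Per-phase width (biphasic), us.
#' @param interphase_us Interphase interval (biphasic), us.
#' @param repetition_hz Pulse repetition frequency (biphasic), Hz.
#' @param n_pulses Pulse count per trial (biphasic).
#' @param f1_hz,f2_hz Carrier frequencies (sinusoid pair), Hz.
#' @param sample_rate Waveform sample rate, Hz.
#' @return An object of class `stim_waveform`.
#' @export
stim_waveform <- function(kind = c("biphasic_pulse_train", "tis_sine_pair"),
                          amplitude_uA = 200, phase_width_us = 150,
                          interphase_us = 53, repetition_hz = 20,
                          n_pulses = 100, f1_hz = 2000, f2_hz = 2002,
                          sample_rate = 1e6) {
  kind <- match.arg(kind)
  structure(list(kind = kind, amplitude_uA = amplitude_uA,
                 phase_width_us = phase_width_us,
                 interphase_us = interphase_us,
                 repetition_hz = repetition_hz, n_pulses = n_pulses,
                 f1_hz = f1_hz, f2_hz = f2_hz, sample_rate = sample_rate),
            class = "stim_waveform")
}

#' Charge, charge density, and Shannon safety metric
#'
#' Per-phase charge of a rectangular biphasic pulse is `I * pw`; per
#' half-cycle charge of a sinusoidal carrier is `I_peak / (pi * f)`. Charge
#' density divides by the electrode's geometric area; the Shannon criterion
#' statistic is `k = log10(density uC/cm^2) + log10(charge uC)`.
#'
#' @param wave A [stim_waveform()].
#' @param electrode_area_cm2 Geometric electrode area in cm^2; see
#'   [synthetic_electrode_area_cm2()] for the back-derived fixture value.
#' @return List with `charge_uC`, `density_mC_cm2`, `shannon_k`.
#' @export
charge_metrics <- function(wave, electrode_area_cm2) {
  stopifnot(inherits(wave, "stim_waveform"))
  if (electrode_area_cm2 <= 0) stop("electrode area must be positive")
  q_uC <- if (wave$kind == "biphasic_pulse_train") {
    wave$amplitude_uA * wave$phase_width_us * 1e-6   # uA * s = uC
  } else {
    wave$amplitude_uA / (pi * wave$f1_hz)            # half-cycle of carrier
  }
  density_uC_cm2 <- q_uC / electrode_area_cm2
  list(charge_uC = q_uC,
       density_mC_cm2 = density_uC_cm2 / 1000,
       shannon_k = log10(density_uC_cm2) + log10(q_uC))
}

#' Back-derived electrode area (synthetic fixture constant)
#'
#' The cuff's per-contact geometric area is not published; this constant is
#' back-derived so that the documented per-phase charge of a 200 uA / 150 us
#' biphasic pulse (0.03 uC) corresponds to a charge density of
#' 0.01875 mC/cm^2. It is a synthetic reconstruction for worked examples,
#' not a measured value.
#'
#' @return Area in cm^2 (1.6e-3).
#' @export
synthetic_electrode_area_cm2 <- function() 0.03 / 18.75

#' Sample a charge-balanced biphasic pulse train
#'
#' Rectangular cathodic-first pulses: a negative phase and an equal-charge
#' positive phase of `phase_width_us` each, separated by `interphase_us`,
#' repeated at `repetition_hz` for `n_pulses` pulses. Both phases use the
#' same number of samples, so the net integral is exactly zero.
#'
#' @param wave A [stim_waveform()] of kind `"biphasic_pulse_train"`.
#' @return List with `t` (s), `current_uA`, `duration_s` (span of pulse
#'   onsets: `n_pulses / repetition_hz`).
#' @export
biphasic_train <- function(wave) {
  stopifnot(inherits(wave, "stim_waveform"),
            wave$kind == "biphasic_pulse_train")
  sr <- wave$sample_rate
  pw_n <- max(1L, round(wave$phase_width_us * 1e-6 * sr))
  ipi_n <- round(wave$interphase_us * 1e-6 * sr)
  period_n <- round(sr / wave$repetition_hz)
  if (2 * pw_n + ipi_n >= period_n)
    stop("pulses overlap: repetition period must exceed 2*pw + interphase")
  total_n <- period_n * wave$n_pulses
  cur <- numeric(total_n)
  one <- c(rep(-wave$amplitude_uA, pw_n), rep(0, ipi_n),
           rep(wave$amplitude_uA, pw_n))
  for (p in seq_len(wave$n_pulses)) {
    s <- (p - 1L) * period_n
    cur[s + seq_along(one)] <- one
  }
  list(t = (seq_len(total_n) - 1) / sr, current_uA = cur,
       duration_s = wave$n_pulses / wave$repetition_hz)
}
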