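# Pseudo-M/EEG generation under the linear forward model X = A S + E:
# a narrowband oscillatory target source with a smooth, strictly positive
# amplitude envelope is planted among 1/f-spectrum background sources, mixed
# through a (synthetic or user-supplied) lead field, and corrupted by i.i.d.
# Gaussian sensor noise. Because the planted envelope is known exactly, these
# recordings carry ground truth for every downstream labeling and decoding
# step.

one_over_f_noise <- function(n_samples, fs) {
  w <- stats::rnorm(n_samples)
  W <- stats::fft(w)
  f <- seq(0, n_samples - 1) / n_samples * fs
  f <- pmin(f, fs - f)              # two-sided frequency axis
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)  # power ~ 1/f, kill DC
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n_samples
  as.numeric(x / stats::sd(x))
}

smooth_envelope <- function(n_samples, fs, timescale_s) {
  cutoff <- 1 / timescale_s
  if (cutoff >= fs / 2) abort("envelope timescale too short for this sampling rate")
  # rectified lowpassed Gaussian noise: half-normal marginal (coefficient of
  # variation ~0.76, the waxing-and-waning look of real band-power envelopes)
  # fluctuating on the requested timescale
  e <- abs(lowpass_vec(stats::rnorm(n_samples), cutoff, fs, order = 4))
  # offset so the envelope never collapses: min > 0.1 * mean avoids
  # degenerate zero-power epochs
  m <- mean(e); mn <- min(e)
  if (mn <= 0.1 * m) e <- e + (0.1 * m - mn) / 0.9 + 1e-3 * abs(m)
  e / mean(e)
}

#' Simulate neural source time courses
#'
#' Generates `n_sources` source signals: one narrowband oscillatory target --
#' a sinusoidal carrier at the center of `target_band_hz`, amplitude-modulated
#' by a smooth positive random envelope (lowpass-filtered rectified Gaussian
#' noise with cutoff `1/envelope_timescale_s`) -- and `n_sources - 1`
#' background sources with a 1/f power spectrum. The planted envelope is
#' returned as ground truth; it is normalized to unit mean, and background
#' rows are standardized to unit variance, so the target-to-background power
#' ratio is controlled at the mixing stage.
#'
#' @param n_sources Number of sources (>= 1); the target occupies row
#'   `target_index`.
#' @param n_samples Number of time samples (>= `fs`).
#' @param fs Sampling rate in Hz.
#' @param target_band_hz Length-2 band (Hz) containing the carrier; must lie
#'   strictly inside (0, fs/2).
#' @param envelope_timescale_s Timescale of envelope fluctuations in seconds;
#'   `Inf` forces a constant (unit) envelope, making the target a pure
#'   sinusoid.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param target_index Row index (1-based) of the planted target source.
#' @return A `source_activity` object with fields `S`, `fs`, `target_index`,
#'   `true_envelope`.
#' @examples
#' src <- simulate_sources(5, 2400, fs = 120, seed = 1)
#' @export
simulate_sources <- function(n_sources, n_samples, fs,
                             target_band_hz = c(8, 12),
                             envelope_timescale_s = 2,
                             seed = NULL, target_index = 1L) {
  n_sources <- assert_count(n_sources, "n_sources")
  n_samples <- assert_count(n_samples, "n_samples")
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (n_samples < fs) abort("`n_samples` must cover at least one second")
  if (length(target_band_hz) != 2L || target_band_hz[1] <= 0 ||
      target_band_hz[2] >= fs / 2 || target_band_hz[1] >= target_band_hz[2])
    abort("`target_band_hz` must lie strictly inside (0, fs/2)")
  target_index <- assert_count(target_index, "target_index")
  if (target_index > n_sources) abort("`target_index` exceeds `n_sources`")

  run_seeded(seed, {
    t <- seq(0, n_samples - 1) / fs
    f0 <- mean(target_band_hz)
    env <- if (is.infinite(envelope_timescale_s)) rep(1, n_samples)
           else smooth_envelope(n_samples, fs, envelope_timescale_s)
    phase <- stats::runif(1, 0, 2 * pi)
    S <- matrix(0, n_sources, n_samples)
    S[target_index, ] <- env * sin(2 * pi * f0 * t + phase)
    bg <- setdiff(seq_len(n_sources), target_index)
    for (i in bg) S[i, ] <- one_over_f_noise(n_samples, fs)
    new_source_activity(S, fs, target_index, env,
                        meta = list(seed = seed, target_band_hz = target_band_hz,
                                    envelope_timescale_s = envelope_timescale_s))
  })
}

#' Project sources to the sensor space
#'
#' Applies the linear forward model `X = A S + E`, with `E` i.i.d. Gaussian
#' sensor noise of standard deviation `spec$sensor_noise_sd` (isotropic noise
#' covariance, a scaled identity).
#'
#' @param sources A `source_activity` object.
#' @param spec A [forward_spec()]; `ncol(spec$A)` must equal the number of
#'   sources.
#' @return An [eeg_recording()].
#' @export
mix_to_sensors <- function(sources, spec) {
  if (!inherits(sources, "source_activity")) abort("`sources` must be a source_activity")
  if (!inherits(spec, "forward_spec")) abort("`spec` must be a forward_spec")
  if (ncol(spec$A) != nrow(sources$S))
    abort(sprintf("lead field has %d columns but there are %d sources",
                  ncol(spec$A), nrow(sources$S)))
  X <- spec$A %*% sources$S
  if (spec$sensor_noise_sd > 0) {
    E <- run_seeded(spec$seed,
                    matrix(stats::rnorm(length(X), sd = spec$sensor_noise_sd),
                           nrow(X), ncol(X)))
    X <- X + E
  }
  eeg_recording(X, sources$fs)
}

#' Generate a smooth synthetic lead field
#'
#' Columns are spatially smooth random patterns (white Gaussian weights
#' convolved with a Gaussian kernel along the channel axis) with unit l2
#' norm. A stand-in for an anatomical head model when none is available.
#'
#' @param n_channels Number of sensors (>= 2).
#' @param n_sources Number of sources (>= 1).
#' @param smoothness Kernel standard deviation in channel-index units.
#' @param seed Integer seed.
#' @return A [forward_spec()] with `sensor_noise_sd = 0`.
#' @export
make_leadfield <- function(n_channels, n_sources, smoothness = 2, seed = NULL) {
  n_channels <- assert_count(n_channels, "n_channels", min = 2L)
  n_sources <- assert_count(n_sources, "n_sources")
  assert_number(smoothness, "smoothness", lower = 0)
  run_seeded(seed, {
    A <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
    if (smoothness > 0) {
      half <- max(1L, ceiling(3 * smoothness))
      kern <- stats::dnorm(seq(-half, half), sd = smoothness)
      kern <- kern / sum(kern)
      A <- apply(A, 2L, function(col) {
        padded <- c(rep(col[1], half), col, rep(col[n_channels], half))
        as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n_channels)]
      })
    }
    A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
    forward_spec(A, sensor_noise_sd = 0, seed = seed)
  })
}

#' Load a lead field from a delimited text file
#'
#' Reads a numeric channels-by-sources matrix from whitespace- or
#' comma-delimited text. Columns are loaded unmodified (no renormalization).
#'
#' @param path Path to the file.
#' @return A [forward_spec()] with `sensor_noise_sd = 0`.
#' @export
load_leadfield <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("lead-field file is empty")
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
  rows <- lapply(lines, function(l) {
    fields <- strsplit(l, sep)[[1]]
    fields <- fields[nzchar(trimws(fields))]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) abort("lead-field file contains non-numeric fields")
    vals
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) abort("lead-field file has ragged rows")
  A <- do.call(rbind, rows)
  forward_spec(A, sensor_noise_sd = 0)
}

#' Sensor-noise level for a requested broadband SNR
#'
#' Converts a signal-to-noise ratio in dB into the per-sample Gaussian noise
#' standard deviation matching `mean((A S)^2) / sd^2 = 10^(snr_db/10)`.
#'
#' @param A Lead-field matrix or [forward_spec()].
#' @param S Source matrix or `source_activity`.
#' @param snr_db Requested broadband SNR in decibels.
#' @return Noise standard deviation (same units as `A %*% S`).
#' @export
noise_sd_from_snr <- function(A, S, snr_db) {
  if (inherits(A, "forward_spec")) A <- A$A
  if (inherits(S, "source_activity")) S <- S$S
  assert_number(snr_db, "snr_db")
  sig <- A %*% S
  sqrt(mean(sig^2) / 10^(snr_db / 10))
}
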