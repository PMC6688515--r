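# S3 containers: continuous recordings, source activity, forward models,
# source estimates. Deliberately plain lists with validators, in the style of
# base R modelling objects.

#' Continuous multichannel recording
#'
#' Container for a continuous M/EEG recording: a channels-by-samples numeric
#' matrix, its sampling rate, and channel names.
#'
#' @param X Numeric matrix, channels in rows, samples in columns (nominal
#'   unit: microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel; generated when
#'   omitted.
#' @return An object of class `eeg_recording` with elements `X`, `fs`,
#'   `channel_names`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100)
#' @export
eeg_recording <- function(X, fs, channel_names = NULL) {
  assert_finite_matrix(X, "X")
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  channel_names <- channel_names %||% sprintf("Ch%02d", seq_len(nrow(X)))
  if (length(channel_names) != nrow(X))
    abort("`channel_names` must have one entry per channel")
  structure(list(X = X, fs = fs, channel_names = as.character(channel_names)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$X), ncol(x$X), x$fs, ncol(x$X) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$X)

new_source_activity <- function(S, fs, target_index, true_envelope, meta = list()) {
  structure(list(S = S, fs = fs, target_index = as.integer(target_index),
                 true_envelope = true_envelope, meta = meta),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat(sprintf("<source_activity> %d sources x %d samples @ %g Hz, target row %d\n",
              nrow(x$S), ncol(x$S), x$fs, x$target_index))
  invisible(x)
}

#' Forward model specification
#'
#' Bundles a mixing (lead-field) matrix with the sensor-noise level used when
#' projecting sources to the sensor space. Columns of `A` are spatial
#' patterns: the sensor-space footprint of each source.
#'
#' @param A Numeric matrix, channels by sources; no column may be all-zero.
#' @param sensor_noise_sd Standard deviation of the i.i.d. Gaussian sensor
#'   noise added on top of `A %*% S`, in the units of the mixed signal.
#' @param seed Optional integer seed for the sensor-noise stream.
#' @return Object of class `forward_spec`.
#' @export
forward_spec <- function(A, sensor_noise_sd = 0, seed = NULL) {
  assert_finite_matrix(A, "A")
  if (any(colSums(A^2) == 0)) abort("`A` has an all-zero column")
  assert_number(sensor_noise_sd, "sensor_noise_sd", lower = 0)
  structure(list(A = A, sensor_noise_sd = sensor_noise_sd, seed = seed),
            class = "forward_spec")
}

#' @export
print.forward_spec <- function(x, ...) {
  cat(sprintf("<forward_spec> %d channels x %d sources, sensor noise sd %g\n",
              nrow(x$A), ncol(x$A), x$sensor_noise_sd))
  invisible(x)
}

new_source_estimate <- function(S_hat, method, fs, unmixing = NULL,
                                leadfield_ref = NULL, extra = list()) {
  structure(c(list(S_hat = S_hat, method = method, fs = fs,
                   unmixing = unmixing, leadfield_ref = leadfield_ref), extra),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> method %s: %d sources x %d samples\n",
              x$method, nrow(x$S_hat), ncol(x$S_hat)))
  invisible(x)
}

as_signal_matrix <- function(x, name = "x") {
  if (inherits(x, "eeg_recording")) return(x$X)
  if (inherits(x, "source_estimate")) return(x$S_hat)
  if (is.matrix(x)) return(x)
  abort(sprintf("`%s` must be an eeg_recording, source_estimate or matrix", name))
}

signal_fs <- function(x, fs = NULL) {
  if (inherits(x, c("eeg_recording", "source_estimate"))) x$fs else fs
}
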