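# Post-hoc label extraction: narrowband filtering, Hilbert envelope of the
# selected source, artifact screening, epoching, and percentile
# discretization. The pipeline is deterministic: identical recording and
# configuration yield bit-identical labels, which is the point of deriving
# labels from a subspace of the recording itself.

#' Band-power envelope via the analytic signal
#'
#' Returns `|H(s)|`, the magnitude of the Hilbert analytic signal, i.e. the
#' instantaneous amplitude of a narrowband oscillation. Output length equals
#' input length and is non-negative everywhere.
#'
#' @param s_z Numeric vector (a bandpassed source time course), length >= 8.
#' @return Non-negative envelope vector.
#' @examples
#' t <- seq(0, 10, by = 1 / 120)
#' env <- extract_envelope(2 * sin(2 * pi * 10 * t)) # ~= 2 away from the edges
#' @export
extract_envelope <- function(s_z) {
  if (length(s_z) < 8L) abort("input must have at least 8 samples")
  if (!all(is.finite(s_z))) abort("input contains non-finite values")
  n <- length(s_z)
  H <- stats::fft(s_z)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(H * h, inverse = TRUE) / n
  Mod(analytic)
}

#' Mark artifactual windows by peak-to-peak amplitude
#'
#' The recording is bandpass filtered to `detect_band` (5th-order Butterworth,
#' zero-phase), cut into the same non-overlapping windows used for epoching,
#' and a window is rejected iff any channel's peak-to-peak amplitude strictly
#' exceeds `ptp_threshold_uv`.
#'
#' @param X An [eeg_recording()] or channels-by-samples matrix.
#' @param ptp_threshold_uv Rejection threshold in microvolts (default 80).
#' @param detect_band Band used for outlier screening (default 0.7--25 Hz);
#'   `NULL` skips the filtering step (useful for testing threshold semantics).
#' @param window_s Window length in seconds.
#' @param fs Sampling rate when `X` is a plain matrix.
#' @return Logical vector, one element per complete window; `TRUE` = rejected.
#' @export
detect_artifacts <- function(X, ptp_threshold_uv = 80, detect_band = c(0.7, 25),
                             window_s = 1.0, fs = NULL) {
  assert_number(ptp_threshold_uv, "ptp_threshold_uv", lower = 0, strict_lower = TRUE)
  fs <- signal_fs(X, fs)
  if (is.null(fs)) abort("`fs` is required")
  Xm <- as_signal_matrix(X, "X")
  if (!is.null(detect_band))
    Xm <- bandpass(Xm, detect_band[1], detect_band[2], fs = fs)
  spw <- round(fs * window_s)
  n_win <- floor(ncol(Xm) / spw)
  vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * spw + 1):(w * spw)
    ptp <- apply(Xm[, idx, drop = FALSE], 1L, function(ch) max(ch) - min(ch))
    any(ptp > ptp_threshold_uv)
  }, logical(1))
}

#' Segment a recording and its envelope into labeled epochs
#'
#' Cuts the (bandpassed) recording and the continuous envelope into
#' non-overlapping windows starting at the first sample; a trailing partial
#' window is dropped. Windows flagged in `rejected_mask` are removed from the
#' data and the labels alike. The epoch label is the window average of the
#' squared envelope (`label_mode = "power"`, the default) or of the envelope
#' itself (`"amplitude"`).
#'
#' @param X_band Bandpassed [eeg_recording()] or matrix.
#' @param z_cont Per-sample envelope, aligned with `X_band`.
#' @param window_s Window length in seconds.
#' @param rejected_mask Logical mask from [detect_artifacts()]; `NULL` keeps
#'   every window.
#' @param fs Sampling rate when `X_band` is a plain matrix.
#' @param label_mode `"power"` or `"amplitude"`.
#' @return An `epoched_dataset`: `epochs` (kept epochs x channels x samples),
#'   `z_epoch`, `rejected_mask`, `fs`, `window_s`, `label_mode`.
#' @export
epoch_and_label <- function(X_band, z_cont, window_s = 1.0, rejected_mask = NULL,
                            fs = NULL, label_mode = c("power", "amplitude")) {
  label_mode <- match.arg(label_mode)
  fs <- signal_fs(X_band, fs)
  if (is.null(fs)) abort("`fs` is required")
  Xm <- as_signal_matrix(X_band, "X_band")
  if (length(z_cont) != ncol(Xm))
    abort("`X_band` and `z_cont` must be aligned in samples")
  spw <- round(fs * window_s)
  n_win <- floor(ncol(Xm) / spw)
  if (n_win < 1L) abort("recording shorter than one window")
  rejected_mask <- rejected_mask %||% rep(FALSE, n_win)
  if (length(rejected_mask) != n_win)
    abort("`rejected_mask` length does not match the number of windows")
  keep <- which(!rejected_mask)
  if (length(keep) == 0L) abort("no usable epochs after artifact rejection")
  epochs <- array(0, dim = c(length(keep), nrow(Xm), spw))
  z_epoch <- numeric(length(keep))
  for (j in seq_along(keep)) {
    idx <- ((keep[j] - 1) * spw + 1):(keep[j] * spw)
    epochs[j, , ] <- Xm[, idx, drop = FALSE]
    zw <- z_cont[idx]
    z_epoch[j] <- if (label_mode == "power") mean(zw^2) else mean(zw)
  }
  structure(list(epochs = epochs, z_epoch = z_epoch,
                 rejected_mask = rejected_mask, kept = keep,
                 fs = fs, window_s = window_s, label_mode = label_mode),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoched_dataset> %d epochs x %d channels x %d samples (%d rejected)\n",
              d[1], d[2], d[3], sum(x$rejected_mask)))
  invisible(x)
}

#' Discretize continuous labels into percentile classes
#'
#' Binary: class 1 iff the label is at or below the median, class 2 above.
#' Ternary: boundaries at the lower and upper tertile (linear-interpolation
#' percentiles); values tied with a boundary go to the lower class.
#'
#' @param z_epoch Numeric vector of epoch labels.
#' @param scheme `"binary"` or `"ternary"`.
#' @return Integer class labels in `1:2` or `1:3`.
#' @examples
#' discretize_labels(1:10, "binary")  # five 1s then five 2s
#' @export
discretize_labels <- function(z_epoch, scheme = c("binary", "ternary")) {
  scheme <- match.arg(scheme)
  n_classes <- if (scheme == "binary") 2L else 3L
  if (length(z_epoch) < n_classes)
    abort("need at least as many epochs as classes")
  if (diff(range(z_epoch)) == 0)
    abort("labels are all equal: no contrast to discretize")
  breaks <- if (scheme == "binary") stats::median(z_epoch)
            else stats::quantile(z_epoch, c(1, 2) / 3, names = FALSE, type = 7)
  lower_tie_cut(z_epoch, breaks)
}

#' Partition sources into z-variance tertiles
#'
#' Ranks sources of one recording by the variance of their epoch labels and
#' splits them at the lower/upper tertile boundaries into low, medium and
#' high label-variability groups (ties fall to the lower group). With fewer
#' than three sources the assignment is left unset with a warning.
#'
#' @param label_sets A list of label vectors (or of objects carrying
#'   `$z_epoch`), one per source; alternatively a numeric vector of
#'   precomputed label variances.
#' @return Factor with levels `low`, `medium`, `high` (or `NA`s).
#' @export
variance_tertiles <- function(label_sets) {
  vars <- if (is.numeric(label_sets)) label_sets
          else vapply(label_sets, function(l) {
            z <- if (is.list(l)) l$z_epoch else l
            stats::var(z)
          }, numeric(1))
  lev <- c("low", "medium", "high")
  if (length(vars) < 3L) {
    warning("fewer than 3 sources: tertiles left unset")
    return(factor(rep(NA_character_, length(vars)), levels = lev))
  }
  breaks <- stats::quantile(vars, c(1, 2) / 3, names = FALSE, type = 7)
  factor(lev[lower_tie_cut(vars, breaks)], levels = lev)
}

#' Post-hoc label a continuous recording
#'
#' Runs the full labeling pipeline on a continuous recording: (1) screen
#' windows for artifacts on the broadband data; (2) bandpass filter to the
#' target band and project onto the source space (minimum-norm inverse with a
#' lead field, or ICA); (3) select a target source by policy; (4) take the
#' magnitude of its Hilbert transform as the continuous target variable;
#' (5) epoch data and labels, dropping artifactual windows; (6) optionally
#' discretize the epoch labels by percentiles. All configuration, resolved
#' hyperparameters and the selected source index are stored in `$meta`, so
#' the labels can be regenerated from the raw recording alone (see
#' [relabel()]).
#'
#' @param rec An [eeg_recording()].
#' @param inverse `"mne"` (requires `leadfield`) or `"ica"`.
#' @param leadfield Lead-field matrix or [forward_spec()] (mne only).
#' @param band Target frequency band in Hz (default 8--12, the alpha band).
#' @param window_s Epoch length in seconds.
#' @param ptp_reject Peak-to-peak artifact threshold in microvolts; `Inf`
#'   disables rejection.
#' @param detect_band Screening band for artifact detection.
#' @param scheme `"regression"` (continuous labels only), `"binary"` or
#'   `"ternary"`.
#' @param policy,index Target-source selection policy and index, passed to
#'   [select_component()].
#' @param n_components ICA component count (ica only).
#' @param lam Minimum-norm regularization or `"auto"` (mne only).
#' @param label_mode `"power"` or `"amplitude"` epoch label.
#' @param rescale Apply the l2/average-covariance rescaling of
#'   [rescale_sources()] to data-driven sources (default `TRUE` for ica).
#' @param seed Seed governing ICA initialization and random source selection.
#' @return An object of class `posthoc_labels`: the epoched dataset, the
#'   label set (`z_cont`, `z_epoch`, `y_epoch`, `target_source`, `band_hz`),
#'   the source estimate, and a `meta` list sufficient to reproduce the
#'   labels.
#' @export
posthoc_label <- function(rec, inverse = c("mne", "ica"), leadfield = NULL,
                          band = c(8, 12), window_s = 1.0, ptp_reject = 80,
                          detect_band = c(0.7, 25),
                          scheme = c("regression", "binary", "ternary"),
                          policy = "max_band_power", index = NULL,
                          n_components = 20, lam = "auto",
                          label_mode = c("power", "amplitude"),
                          rescale = NULL, seed = NULL) {
  inverse <- match.arg(inverse)
  scheme <- match.arg(scheme)
  label_mode <- match.arg(label_mode)
  if (!inherits(rec, "eeg_recording")) abort("`rec` must be an eeg_recording")

  mask <- if (is.infinite(ptp_reject)) NULL
          else detect_artifacts(rec, ptp_reject, detect_band, window_s)
  Xb <- bandpass(rec, band[1], band[2])

  if (inverse == "mne") {
    if (is.null(leadfield)) abort("`leadfield` is required for the mne inverse")
    est <- mne_inverse(Xb, leadfield, lam = lam)
  } else {
    est <- ica_decompose(Xb, n_components = n_components, seed = seed)
    if (rescale %||% TRUE) est <- rescale_sources(est, Xb)
  }

  target <- select_component(est, policy = policy, index = index,
                             band_hz = band, fs = rec$fs, seed = seed)
  z_cont <- extract_envelope(est$S_hat[target, ])
  ds <- epoch_and_label(Xb, z_cont, window_s, mask, label_mode = label_mode)
  y_epoch <- if (scheme == "regression") NULL
             else discretize_labels(ds$z_epoch, scheme)

  meta <- list(inverse = inverse, band = band, window_s = window_s,
               ptp_reject = ptp_reject, detect_band = detect_band,
               scheme = scheme, label_mode = label_mode,
               n_components = if (inverse == "ica") est$n_components else NULL,
               lambda = if (inverse == "mne") est$lambda else NULL,
               rescale = if (inverse == "ica") rescale %||% TRUE else NULL,
               target_source = target, seed = seed)
  structure(list(epochs = ds,
                 labels = list(z_cont = z_cont, z_epoch = ds$z_epoch,
                               y_epoch = y_epoch, target_source = target,
                               band_hz = band),
                 estimate = est,
                 leadfield = if (inverse == "mne") leadfield else NULL,
                 meta = meta),
            class = "posthoc_labels")
}

#' Regenerate labels from a raw recording and stored metadata
#'
#' Re-runs [posthoc_label()] with the configuration stored in a previous
#' result (including the resolved regularization constant and the selected
#' source index), demonstrating that post-hoc labels are deterministically
#' recoverable from the data alone.
#'
#' @param rec The raw [eeg_recording()].
#' @param fit A `posthoc_labels` object (or its `$meta` plus a lead field).
#' @return A new `posthoc_labels` object; its labels are bit-identical to the
#'   original's.
#' @export
relabel <- function(rec, fit) {
  meta <- if (inherits(fit, "posthoc_labels")) fit$meta else fit
  leadfield <- if (inherits(fit, "posthoc_labels")) fit$leadfield else NULL
  posthoc_label(rec, inverse = meta$inverse, leadfield = leadfield,
                band = meta$band, window_s = meta$window_s,
                ptp_reject = meta$ptp_reject, detect_band = meta$detect_band,
                scheme = meta$scheme, policy = "by_index",
                index = meta$target_source,
                n_components = meta$n_components %||% 20,
                lam = meta$lambda %||% "auto", label_mode = meta$label_mode,
                rescale = meta$rescale, seed = meta$seed)
}

#' @export
print.posthoc_labels <- function(x, ...) {
  d <- dim(x$epochs$epochs)
  cat(sprintf("<posthoc_labels> %s inverse, target source %d, band %g-%g Hz\n",
              x$meta$inverse, x$labels$target_source,
              x$labels$band_hz[1], x$labels$band_hz[2]))
  cat(sprintf("  %d labeled epochs (%d rejected), scheme: %s\n",
              d[1], sum(x$epochs$rejected_mask), x$meta$scheme))
  invisible(x)
}

#' @export
summary.posthoc_labels <- function(object, ...) {
  z <- object$labels$z_epoch
  cat(sprintf("Post-hoc labels (%s inverse)\n", object$meta$inverse))
  cat(sprintf("  epochs: %d kept / %d total\n", length(z),
              length(object$epochs$rejected_mask)))
  cat(sprintf("  z_epoch: mean %.4g, var %.4g\n", mean(z), stats::var(z)))
  if (!is.null(object$labels$y_epoch))
    print(table(class = object$labels$y_epoch))
  invisible(object)
}

#' @export
plot.posthoc_labels <- function(x, ...) {
  z <- x$labels$z_epoch
  graphics::plot(z, type = "l", xlab = "epoch", ylab = "label z",
                 main = "Post-hoc epoch labels", ...)
  if (!is.null(x$labels$y_epoch))
    graphics::points(seq_along(z), z, col = x$labels$y_epoch, pch = 20)
  invisible(x)
}
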