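# Butterworth IIR design in second-order sections and zero-phase filtering.
#
# The design path is the textbook one: analog Butterworth prototype poles,
# frequency pre-warping, analog lowpass/bandpass transform, bilinear transform,
# and grouping of conjugate pole pairs into biquads. Working in second-order
# sections keeps high-order bandpass filters numerically stable, which a single
# transfer-function polynomial of order 2n does not guarantee.

butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

bilinear_map <- function(s, fs) (2 * fs + s) / (2 * fs - s)

# split a self-conjugate set of poles into conjugate (or real) pairs
pair_poles <- function(p, tol = 1e-9) {
  cplx <- p[Im(p) > tol]
  real <- sort(Re(p[abs(Im(p)) <= tol]))
  pairs <- lapply(cplx, function(z) c(z, Conj(z)))
  if (length(real) %% 2L == 1L)
    pairs <- c(pairs, list(c(real[1], NA_complex_))) # first-order section
  if (length(real) > 1L) {
    real2 <- if (length(real) %% 2L == 1L) real[-1] else real
    idx <- seq(1L, length(real2), by = 2L)
    pairs <- c(pairs, lapply(idx, function(i) c(real2[i], real2[i + 1]) + 0i))
  }
  pairs
}

den_from_pair <- function(pr) {
  if (any(is.na(pr))) c(1, -Re(pr[1]), 0)
  else c(1, -Re(pr[1] + pr[2]), Re(pr[1] * pr[2]))
}

sos_response <- function(sos, z) {
  h <- 1 + 0i
  zi1 <- 1 / z
  zi2 <- zi1^2
  for (k in seq_len(nrow(sos))) {
    b <- unname(sos[k, 1:3]); a <- unname(sos[k, 4:6])
    h <- h * (b[1] + b[2] * zi1 + b[3] * zi2) / (a[1] + a[2] * zi1 + a[3] * zi2)
  }
  h
}

#' Design a Butterworth filter as second-order sections
#'
#' Designs a digital Butterworth lowpass, highpass or bandpass filter by
#' bilinear transform of the analog prototype, returned as a matrix of
#' second-order sections (one row per biquad, columns `b0 b1 b2 a0 a1 a2`).
#'
#' @param order Prototype filter order (a bandpass filter of order `n` has
#'   `2n` poles).
#' @param fc Cutoff frequency in Hz (scalar for `low`/`high`, length-2 vector
#'   for `pass`).
#' @param fs Sampling rate in Hz.
#' @param type Filter type.
#' @return Numeric matrix of second-order sections.
#' @examples
#' sos <- butter_sos(5, c(8, 12), fs = 120, type = "pass")
#' @export
butter_sos <- function(order, fc, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  order <- assert_count(order, "order")
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(fc)) || any(fc <= 0) || any(fc >= fs / 2))
    abort("cutoff frequencies must lie strictly between 0 and fs/2")
  p <- butter_prototype_poles(order)
  warp <- function(f) 2 * fs * tan(pi * f / fs)

  if (type %in% c("low", "high")) {
    if (length(fc) != 1L) abort("`fc` must be scalar for low/highpass")
    wc <- warp(fc)
    sp <- if (type == "low") wc * p else wc / p
    zd <- rep(if (type == "low") -1 else 1, order) # zeros at Nyquist resp. DC
    pd <- bilinear_map(sp, fs)
    zref <- if (type == "low") 1 + 0i else -1 + 0i
  } else {
    if (length(fc) != 2L || fc[1] >= fc[2])
      abort("`fc` must be c(low, high) with low < high for a bandpass")
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    sp <- unlist(lapply(p, function(pk) {
      disc <- sqrt((pk * bw)^2 - 4 * w0^2 + 0i)
      c((pk * bw + disc) / 2, (pk * bw - disc) / 2)
    }))
    zd <- rep(c(1, -1), order) # transformed zeros: n at DC, n at Nyquist
    pd <- bilinear_map(sp, fs)
    # unity response at the bilinear image of the analog center frequency
    zref <- bilinear_map(1i * w0, fs)
  }

  pairs <- pair_poles(pd)
  nsec <- length(pairs)
  sos <- matrix(0, nsec, 6)
  nz_plus <- sum(zd > 0) # zeros at z = +1 still to place
  for (k in seq_len(nsec)) {
    first_order <- any(is.na(pairs[[k]]))
    if (type == "low") {
      sos[k, 1:3] <- if (first_order) c(1, 1, 0) else c(1, 2, 1)
    } else if (type == "high") {
      sos[k, 1:3] <- if (first_order) c(1, -1, 0) else c(1, -2, 1)
    } else {
      if (first_order) {
        if (nz_plus > 0) { sos[k, 1:3] <- c(1, -1, 0); nz_plus <- nz_plus - 1 }
        else sos[k, 1:3] <- c(1, 1, 0)
      } else {
        sos[k, 1:3] <- c(1, 0, -1) # one zero at +1, one at -1
        nz_plus <- nz_plus - 1
      }
    }
    sos[k, 4:6] <- den_from_pair(pairs[[k]])
  }
  g <- abs(sos_response(sos, zref))
  sos[1, 1:3] <- sos[1, 1:3] / g
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# single biquad, direct form I, zero initial conditions; the recursion runs in
# C via stats::filter
apply_biquad <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)
  v <- as.numeric(v[-(1:2)])
  if (a[2] == 0 && a[3] == 0) v
  else as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filter <- function(sos, x) {
  for (k in seq_len(nrow(sos))) x <- apply_biquad(x, sos[k, 1:3], sos[k, 4:6])
  x
}

#' Zero-phase filtering with second-order sections
#'
#' Applies the filter forward and backward (cancelling the phase response and
#' squaring the magnitude response), with odd-reflection padding at both ends
#' to suppress startup transients.
#'
#' @param sos Second-order sections from [butter_sos()].
#' @param x Numeric vector.
#' @param padlen Number of reflected samples prepended/appended; defaults to
#'   `min(n - 1, 12 * nrow(sos))`.
#' @return Filtered vector of the same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (n < 8L) abort("input too short to filter")
  if (!all(is.finite(x))) abort("input contains non-finite values")
  pad <- padlen %||% min(n - 1L, max(24L, 12L * nrow(sos)))
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- c(head_ext, x, tail_ext)
  y <- sos_filter(sos, y)
  y <- rev(sos_filter(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Bandpass filter a recording
#'
#' Zero-phase 5th-order Butterworth bandpass, the narrowband step that
#' precedes source projection and envelope extraction (default band 8--12 Hz,
#' the alpha band).
#'
#' @param x An [eeg_recording()] or a channels-by-samples numeric matrix.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz; taken from `x` when it is a recording.
#' @param order Butterworth prototype order.
#' @return Object of the same type as `x`, filtered per channel.
#' @export
bandpass <- function(x, low_hz, high_hz, fs = NULL, order = 5) {
  is_rec <- inherits(x, "eeg_recording")
  X <- if (is_rec) x$X else x
  fs <- if (is_rec) x$fs else fs
  if (is.null(fs)) abort("`fs` must be supplied for a plain matrix")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    abort("band edges must satisfy 0 < low < high < fs/2")
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  assert_finite_matrix(X, "x")
  sos <- butter_sos(order, c(low_hz, high_hz), fs, type = "pass")
  Y <- t(apply(X, 1L, function(ch) sos_filtfilt(sos, ch)))
  if (vec) return(drop(Y))
  if (is_rec) {
    x$X <- Y
    x
  } else Y
}

lowpass_vec <- function(x, cutoff_hz, fs, order = 4) {
  sos <- butter_sos(order, cutoff_hz, fs, type = "low")
  sos_filtfilt(sos, x)
}
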