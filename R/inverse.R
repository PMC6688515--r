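# Sensor-to-source mapping: anatomically constrained minimum-norm estimation
# (ridge-type inverse of the lead field) and data-driven independent component
# analysis, plus the source rescaling and target-selection policies used by
# the labeling pipeline.

default_lambda_grid <- function() 10^seq(-6, 2, length.out = 30)

#' Minimum-norm source estimate
#'
#' Computes the l2-regularized inverse solution
#' `S = t(A) (I + lambda A t(A))^-1 X` under the convention of an identity
#' noise covariance. Two algebraic forms are provided: `"plain"` is the
#' expression above; `"ridge"` is the minimizer of
#' `lambda * ||X - A S||^2 + ||S||^2`, which equals `lambda` times the plain
#' form. The two differ only by a global positive factor, which leaves any
#' envelope-derived label *order* untouched; `"plain"` is the default.
#'
#' @param X An [eeg_recording()] or channels-by-samples matrix.
#' @param A Lead field (channels by sources) or [forward_spec()].
#' @param lam Regularization scalar > 0, or `"auto"` to select by generalized
#'   cross-validation over `lambda_grid`.
#' @param lambda_grid Candidate grid used when `lam = "auto"` (strictly
#'   positive, sorted ascending).
#' @param form `"plain"` or `"ridge"` (see Details).
#' @return A `source_estimate` with `method = "mne"`; the resolved `lambda`
#'   is stored in the result.
#' @examples
#' A <- diag(3)
#' X <- matrix(rnorm(30), 3)
#' est <- mne_inverse(X, A, lam = 1) # each row shrunk to X/2
#' @export
mne_inverse <- function(X, A, lam = "auto", lambda_grid = default_lambda_grid(),
                        form = c("plain", "ridge")) {
  form <- match.arg(form)
  fs <- signal_fs(X)
  Xm <- as_signal_matrix(X, "X")
  if (!all(is.finite(Xm))) abort("`X` contains non-finite values")
  if (inherits(A, "forward_spec")) A <- A$A
  assert_finite_matrix(A, "A")
  if (nrow(A) != nrow(Xm))
    abort("`A` must have one row per channel of `X`")
  if (identical(lam, "auto"))
    lam <- select_lambda_gcv(Xm, A, lambda_grid)
  assert_number(lam, "lam", lower = 0, strict_lower = TRUE)
  M <- diag(nrow(A)) + lam * tcrossprod(A)
  S_hat <- crossprod(A, solve(M, Xm))
  if (form == "ridge") S_hat <- lam * S_hat
  new_source_estimate(S_hat, "mne", fs,
                      leadfield_ref = sprintf("%dx%d lead field", nrow(A), ncol(A)),
                      extra = list(lambda = lam, form = form))
}

#' Select the regularization constant by generalized cross-validation
#'
#' Evaluates `GCV(lambda) = (||X - H X||_F^2 / N_t) /
#' (tr(I - H) / N_c)^2` with the standard ridge influence matrix
#' `H = A t(A) (A t(A) + lambda I)^-1`, and returns the grid value minimizing
#' it: noise-free data drive lambda to the small end of the grid, pure noise
#' to the large end. Ties are broken toward the larger (more conservative)
#' lambda.
#'
#' @inheritParams mne_inverse
#' @return The selected lambda (scalar).
#' @export
select_lambda_gcv <- function(X, A, lambda_grid = default_lambda_grid()) {
  Xm <- as_signal_matrix(X, "X")
  if (inherits(A, "forward_spec")) A <- A$A
  if (length(lambda_grid) == 0L) abort("`lambda_grid` is empty")
  if (any(lambda_grid <= 0) || is.unsorted(lambda_grid))
    abort("`lambda_grid` must be strictly positive and sorted ascending")
  n_c <- nrow(Xm); n_t <- ncol(Xm)
  AAt <- tcrossprod(A)
  scores <- vapply(lambda_grid, function(lam) {
    H <- AAt %*% solve(AAt + lam * diag(n_c))
    denom <- sum(diag(diag(n_c) - H)) / n_c
    if (denom <= 0) {
      warning(sprintf("lambda = %g skipped: non-positive effective residual dof", lam))
      return(NA_real_)
    }
    resid <- Xm - H %*% Xm
    (sum(resid^2) / n_t) / denom^2
  }, numeric(1))
  if (all(is.na(scores))) abort("GCV failed for every lambda in the grid")
  best <- max(which(scores == min(scores, na.rm = TRUE)))
  lambda_grid[best]
}

# fixed-point fastICA, log-cosh contrast, deflation scheme
fastica_deflation <- function(Z, n_comp, max_iter = 500, tol = 1e-6) {
  n <- ncol(Z)
  W <- matrix(0, n_comp, n_comp)
  for (i in seq_len(n_comp)) {
    w <- stats::rnorm(n_comp)
    w <- w / sqrt(sum(w^2))
    for (iter in seq_len(max_iter)) {
      u <- drop(crossprod(w, Z))
      g <- tanh(u)
      w_new <- drop(Z %*% g) / n - mean(1 - g^2) * w
      if (i > 1L) {
        prev <- W[seq_len(i - 1L), , drop = FALSE]
        w_new <- w_new - drop(crossprod(prev, prev %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      conv <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (conv < tol) break
    }
    W[i, ] <- w
  }
  W
}

#' Independent component decomposition
#'
#' Estimates an unmixing matrix `Phi` (components by channels) by fastICA
#' with the log-cosh contrast and deflation, such that the rows of
#' `S_hat = Phi %*% X` are maximally non-Gaussian. The decomposition is
#' deterministic under `seed`. Each row's sign is fixed so that its skewness
#' is non-negative (envelope extraction is sign-invariant; the convention is
#' for reproducibility only).
#'
#' @param X An [eeg_recording()] or channels-by-samples matrix.
#' @param n_components Number of components; defaults to 20 and is clipped to
#'   the channel count with a warning.
#' @param seed Integer seed for the random initialization.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param fs Sampling rate when `X` is a plain matrix (used only for the
#'   short-recording warning).
#' @return A `source_estimate` with `method = "ica"` and the unmixing matrix
#'   in `$unmixing`.
#' @export
ica_decompose <- function(X, n_components = 20, seed = NULL,
                          max_iter = 500, tol = 1e-6, fs = NULL) {
  fs <- signal_fs(X, fs)
  Xm <- as_signal_matrix(X, "X")
  assert_finite_matrix(Xm, "X")
  n_components <- assert_count(n_components, "n_components")
  n_c <- nrow(Xm)
  if (n_components > n_c) {
    warning(sprintf("n_components clipped from %d to the %d available channels",
                    n_components, n_c))
    n_components <- n_c
  }
  if (!is.null(fs) && ncol(Xm) / fs < 30)
    warning("recording shorter than 30 s; ICA estimates may be unstable")

  mu <- rowMeans(Xm)
  Xc <- Xm - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  rank <- sum(eg$values > 1e-10 * eg$values[1])
  if (rank < n_components)
    abort(sprintf("data rank is %d, below the %d requested components",
                  rank, n_components))
  d <- eg$values[seq_len(n_components)]
  U <- eg$vectors[, seq_len(n_components), drop = FALSE]
  K <- diag(1 / sqrt(d), n_components) %*% t(U)       # whitening
  Z <- K %*% Xc
  W <- run_seeded(seed, fastica_deflation(Z, n_components, max_iter, tol))
  Phi <- W %*% K
  # sign convention: non-negative skewness of the centered component
  Sc <- Phi %*% Xc
  sk <- apply(Sc, 1L, function(s) mean((s - mean(s))^3))
  flip <- ifelse(sk < 0, -1, 1)
  Phi <- Phi * flip
  new_source_estimate(Phi %*% Xm, "ica", fs, unmixing = Phi,
                      extra = list(seed = seed, n_components = n_components))
}

#' Rescale data-driven sources by their average channel covariance
#'
#' ICA leaves the scale of each source undetermined. Each source row is first
#' normalized to unit l2 norm and then multiplied by the mean, over channels,
#' of its inner product with each channel's time course:
#' `s_i <- (1/N_c * sum_c <s_i, x_c>) * s_i`. Zero-norm rows are skipped with
#' a warning, and rows that come out identically zero (orthogonal to every
#' channel) are flagged in the `"flagged"` attribute.
#'
#' @param S_hat A `source_estimate` or sources-by-samples matrix.
#' @param X The recording the sources were estimated from (same sample
#'   count).
#' @return Object of the same type as `S_hat` with rescaled rows.
#' @export
rescale_sources <- function(S_hat, X) {
  est <- inherits(S_hat, "source_estimate")
  S <- if (est) S_hat$S_hat else S_hat
  Xm <- as_signal_matrix(X, "X")
  if (ncol(S) != ncol(Xm)) abort("`S_hat` and `X` must share the sample count")
  flagged <- integer(0)
  for (i in seq_len(nrow(S))) {
    nrm <- sqrt(sum(S[i, ]^2))
    if (nrm == 0) {
      warning(sprintf("source %d has zero norm; skipped", i))
      flagged <- c(flagged, i)
      next
    }
    u <- S[i, ] / nrm
    fac <- mean(Xm %*% u)            # mean over channels of <u, x_c>
    S[i, ] <- fac * u
    if (fac == 0) flagged <- c(flagged, i)
  }
  out <- if (est) { S_hat$S_hat <- S; S_hat } else S
  attr(out, "flagged") <- flagged
  out
}

#' Select the target source
#'
#' Picks the source whose band-power envelope will define the labels. The
#' choice is a policy hook: a fixed index, a seeded random draw, or the row
#' with highest mean power after bandpass filtering to a band of interest.
#'
#' @param S_hat A `source_estimate` or sources-by-samples matrix.
#' @param policy One of `"random"`, `"by_index"`, `"max_band_power"`.
#' @param index Row index for `"by_index"`.
#' @param band_hz Length-2 band for `"max_band_power"`.
#' @param fs Sampling rate when `S_hat` is a plain matrix.
#' @param seed Seed for the `"random"` policy.
#' @return The selected row index (integer).
#' @export
select_component <- function(S_hat, policy = c("random", "by_index", "max_band_power"),
                             index = NULL, band_hz = NULL, fs = NULL, seed = NULL) {
  policy <- match.arg(policy)
  S <- if (inherits(S_hat, "source_estimate")) S_hat$S_hat else S_hat
  fs <- signal_fs(S_hat, fs)
  n_s <- nrow(S)
  switch(policy,
    by_index = {
      index <- assert_count(index, "index")
      if (index > n_s) abort("`index` out of range")
      index
    },
    random = run_seeded(seed, sample.int(n_s, 1L)),
    max_band_power = {
      if (is.null(band_hz) || is.null(fs))
        abort("`band_hz` and `fs` are required for max_band_power")
      p <- apply(S, 1L, function(s)
        mean(bandpass(s, band_hz[1], band_hz[2], fs = fs)^2))
      which.max(p)
    })
}
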