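# Source power comodulation: a supervised spatial filter whose projected
# epoch-wise band power maximally covaries with a continuous target variable.
# The maximizer solves the generalized eigenvalue problem Cz w = lambda C w,
# where Cz is the z-weighted mean of the epoch covariances.

#' Fit a source power comodulation (SPoC) filter
#'
#' Builds `C`, the mean over epochs of `X(e) t(X(e)) / T`, and `Cz`, the same
#' mean weighted by the target labels (standardized to zero mean and unit
#' variance by default), and returns the generalized eigenvector of `Cz`
#' versus `C` with the largest eigenvalue. The filter is l2-normalized; its
#' orientation is fixed so that the associated spatial pattern `C %*% w` has
#' a positive leading coefficient. Predicted labels for new epochs are the
#' per-epoch variances of the filtered time course, whose training-set
#' covariance with the target is non-negative by construction (the largest
#' eigenvalue is the maximal covariance).
#'
#' @param epochs An `epoched_dataset` or 3-d array (epochs x channels x
#'   samples), bandpassed to the band of interest.
#' @param z_epoch Continuous epoch labels with positive variance.
#' @param standardize Standardize `z_epoch` before weighting (default
#'   `TRUE`); `FALSE` uses the raw labels as printed in the eigenproblem.
#' @return An object of class `spoc_model` with `w`, `pattern`, `eigenvalue`,
#'   `C`, `Cz`.
#' @seealso [predict.spoc_model()]
#' @export
fit_spoc <- function(epochs, z_epoch, standardize = TRUE) {
  epochs <- epoch_array(epochs)
  n <- dim(epochs)[1]
  if (length(z_epoch) != n) abort("`z_epoch` must have one label per epoch")
  if (stats::var(z_epoch) == 0) abort("`z_epoch` has zero variance")
  if (n < dim(epochs)[2])
    warning("fewer epochs than channels; SPoC estimates may be unstable")
  z <- if (standardize) (z_epoch - mean(z_epoch)) / stats::sd(z_epoch) else z_epoch
  Tn <- dim(epochs)[3]
  C <- 0; Cz <- 0
  for (e in seq_len(n)) {
    Ce <- tcrossprod(epoch_mat(epochs, e)) / Tn
    C <- C + Ce
    Cz <- Cz + z[e] * Ce
  }
  C <- C / n; Cz <- Cz / n
  Wh <- whitener(C)
  M <- crossprod(Wh, Cz) %*% Wh
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  w <- drop(Wh %*% eg$vectors[, 1L])
  w <- w / sqrt(sum(w^2))
  pattern <- drop(C %*% w)
  if (pattern[which.max(abs(pattern))] < 0) {
    w <- -w
    pattern <- -pattern
  }
  structure(list(w = w, pattern = pattern / sqrt(sum(pattern^2)),
                 eigenvalue = eg$values[1L], C = C, Cz = Cz,
                 standardize = standardize),
            class = "spoc_model")
}

#' @export
#' @describeIn fit_spoc Per-epoch variance of the filtered time course, the
#'   SPoC estimate of the target variable.
#' @param object A fitted `spoc_model`.
#' @param newdata Epoch array or `epoched_dataset`.
#' @param ... Unused.
predict.spoc_model <- function(object, newdata, ...) {
  epochs <- epoch_array(newdata)
  n <- dim(epochs)[1]
  vapply(seq_len(n), function(e) {
    s <- drop(crossprod(object$w, epoch_mat(epochs, e)))
    sum((s - mean(s))^2) / (length(s) - 1)
  }, numeric(1))
}

#' @export
print.spoc_model <- function(x, ...) {
  cat(sprintf("<spoc_model> %d channels, leading eigenvalue %.4f\n",
              length(x$w), x$eigenvalue))
  invisible(x)
}

#' @export
coef.spoc_model <- function(object, ...) object$w
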