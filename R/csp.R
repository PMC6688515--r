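# Common spatial patterns: supervised spatial filters maximizing the
# band-power ratio between two classes, obtained from the generalized
# eigenvalue problem (C1 - C2) w = lambda C w with C the pooled class
# covariance.

epoch_array <- function(epochs) {
  if (inherits(epochs, "epoched_dataset")) epochs <- epochs$epochs
  if (length(dim(epochs)) != 3L)
    abort("`epochs` must be a 3-d array (epochs x channels x samples)")
  epochs
}

# one epoch as a channels x samples matrix (dims survive single channels)
epoch_mat <- function(epochs, e) {
  matrix(epochs[e, , ], dim(epochs)[2], dim(epochs)[3])
}

class_covariance <- function(epochs, idx) {
  Tn <- dim(epochs)[3]
  C <- 0
  for (e in idx) C <- C + tcrossprod(epoch_mat(epochs, e)) / Tn
  C / length(idx)
}

# symmetric whitening with an eigenvalue floor for numerical rank control
whitener <- function(C, floor_rel = 1e-10) {
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, floor_rel * max(eg$values))
  eg$vectors %*% diag(1 / sqrt(d), length(d))
}

#' Fit common spatial patterns with a shrinkage-LDA classifier
#'
#' Estimates class spatial covariances `C1`, `C2` as the mean over class
#' epochs of `X(e) t(X(e))` (epochs are assumed bandpassed, hence
#' approximately zero-mean), solves the generalized eigenvalue problem of
#' `C1 - C2` against the pooled covariance `C = C1 + C2`, and retains the two
#' eigenvectors belonging to the largest and smallest eigenvalues. A
#' regularized LDA on the (log-)variance features of the filtered epochs
#' turns the filters into a classifier.
#'
#' @param epochs An `epoched_dataset` or 3-d array (epochs x channels x
#'   samples), bandpassed to the band of interest.
#' @param y Binary integer labels (exactly two classes, each with at least
#'   two epochs).
#' @param log_features Log-transform the variance features before LDA
#'   (default `TRUE`).
#' @param fit_classifier Train the rLDA stage (default `TRUE`).
#' @return An object of class `csp_model` with `W_full` (all filters,
#'   eigenvalue-ordered), `W_hat` (the two retained filters), `eigenvalues`,
#'   `C1`, `C2`, `C`, and `classifier`.
#' @seealso [csp_features()], [predict.csp_model()]
#' @export
fit_csp <- function(epochs, y, log_features = TRUE, fit_classifier = TRUE) {
  epochs <- epoch_array(epochs)
  classes <- sort(unique(y))
  if (length(classes) != 2L) abort("CSP requires exactly two classes")
  i1 <- which(y == classes[1]); i2 <- which(y == classes[2])
  if (length(i1) < 2L || length(i2) < 2L)
    abort("each class needs at least two epochs")
  C1 <- class_covariance(epochs, i1)
  C2 <- class_covariance(epochs, i2)
  C <- C1 + C2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("pooled covariance is rank deficient; applying shrinkage")
    C1 <- lw_shrink_cov(C1)
    C2 <- lw_shrink_cov(C2)
    C <- C1 + C2
  }
  Wh <- whitener(C)
  M <- crossprod(Wh, (C1 - C2)) %*% Wh
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W_full <- Wh %*% eg$vectors          # eigenvalues sorted descending
  lambda <- eg$values
  W_hat <- W_full[, c(1L, ncol(W_full)), drop = FALSE]
  model <- structure(list(W_full = W_full, W_hat = W_hat, eigenvalues = lambda,
                          C1 = C1, C2 = C2, C = C, classes = classes,
                          log_features = log_features, classifier = NULL),
                     class = "csp_model")
  if (fit_classifier) {
    feats <- csp_features(model, epochs)
    model$classifier <- fit_rlda(feats, y)
  }
  model
}

#' Band-power features of CSP-filtered epochs
#'
#' For each retained filter `w`, the feature of epoch `e` is the variance
#' over time of `t(w) %*% X(e)`, optionally log-transformed.
#'
#' @param model A fitted `csp_model`.
#' @param epochs Epoch array or `epoched_dataset`.
#' @param log Override the model's log-transform setting.
#' @return Numeric matrix (epochs x number of retained filters).
#' @export
csp_features <- function(model, epochs, log = NULL) {
  epochs <- epoch_array(epochs)
  log <- log %||% model$log_features
  n <- dim(epochs)[1]
  W <- model$W_hat
  out <- matrix(0, n, ncol(W))
  for (e in seq_len(n)) {
    s <- crossprod(W, epoch_mat(epochs, e))   # filters x samples
    out[e, ] <- apply(s, 1L, stats::var)
  }
  if (log) out <- base::log(out)
  out
}

#' @export
#' @describeIn fit_csp Continuous classifier scores (monotone in the
#'   posterior of the second class) for new epochs.
#' @param object A fitted `csp_model`.
#' @param newdata Epoch array or `epoched_dataset`.
#' @param ... Unused.
predict.csp_model <- function(object, newdata, ...) {
  if (is.null(object$classifier)) abort("model was fitted without a classifier")
  feats <- csp_features(object, newdata)
  predict(object$classifier, feats)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, eigenvalue range [%.3f, %.3f]\n",
              nrow(x$W_full), min(x$eigenvalues), max(x$eigenvalues)))
  cat(sprintf("  retained filters: 2 (extreme eigenvalues), classifier: %s\n",
              if (is.null(x$classifier)) "none" else "rLDA"))
  invisible(x)
}

#' @export
coef.csp_model <- function(object, ...) object$W_hat
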