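# Linear discriminant analysis with analytic (Ledoit-Wolf) shrinkage of the
# pooled within-class covariance toward a scaled identity. With p features
# and few training epochs the sample covariance is ill-conditioned; the
# shrinkage intensity is estimated in closed form rather than by
# cross-validation.

# Ledoit-Wolf shrinkage of a covariance toward nu * I, intensity from the
# observations themselves (rows of Z are centered observations)
lw_shrinkage_intensity <- function(Z, S) {
  n <- nrow(Z)
  nu <- mean(diag(S))
  d2 <- sum((S - nu * diag(ncol(S)))^2)
  if (d2 == 0) return(0)
  b2 <- 0
  for (i in seq_len(n)) {
    zi <- Z[i, ]
    b2 <- b2 + sum((tcrossprod(zi) - S)^2)
  }
  b2 <- b2 / n^2
  max(0, min(1, b2 / d2))
}

# shrink an externally supplied covariance toward its scaled identity with a
# fixed modest intensity; used as a rank repair for degenerate inputs
lw_shrink_cov <- function(C, gamma = 0.1) {
  nu <- mean(diag(C))
  (1 - gamma) * C + gamma * nu * diag(nrow(C))
}

#' Shrinkage-regularized linear discriminant analysis
#'
#' Two-class LDA whose pooled within-class covariance is replaced by
#' `(1 - gamma) * S + gamma * nu * I`, with `nu` the mean diagonal of `S` and
#' the intensity `gamma` estimated analytically (Ledoit-Wolf) unless given.
#' The returned decision scores are monotone in the posterior probability of
#' the second (larger-labeled) class; a score of zero marks the boundary.
#'
#' @param features Numeric matrix (observations x features).
#' @param y Labels with exactly two distinct values.
#' @param shrinkage Fixed shrinkage intensity in `[0, 1]`, or `NULL` for the
#'   analytic estimate.
#' @return An object of class `rlda` with `w`, `b`, `gamma`, `means`,
#'   `classes`.
#' @export
fit_rlda <- function(features, y, shrinkage = NULL) {
  features <- as.matrix(features)
  classes <- sort(unique(y))
  if (length(classes) != 2L) abort("rLDA requires exactly two classes")
  X1 <- features[y == classes[1], , drop = FALSE]
  X2 <- features[y == classes[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  Z <- rbind(sweep(X1, 2L, m1), sweep(X2, 2L, m2))
  S <- crossprod(Z) / nrow(Z)
  gamma <- shrinkage %||% lw_shrinkage_intensity(Z, S)
  nu <- mean(diag(S))
  C <- (1 - gamma) * S + gamma * nu * diag(ncol(S))
  w <- solve(C, m2 - m1)
  b <- sum(w * (m1 + m2)) / 2
  structure(list(w = w, b = b, gamma = gamma,
                 means = rbind(m1, m2), classes = classes),
            class = "rlda")
}

#' @export
#' @describeIn fit_rlda Continuous decision scores for new feature rows
#'   (positive favors the second class).
#' @param object A fitted `rlda` model.
#' @param newdata Feature matrix.
#' @param ... Unused.
predict.rlda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w) - object$b
}

#' @export
print.rlda <- function(x, ...) {
  cat(sprintf("<rlda> %d features, shrinkage gamma = %.3f\n",
              length(x$w), x$gamma))
  invisible(x)
}
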