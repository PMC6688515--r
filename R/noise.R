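# Controlled label corruption. The noise intensity xi in [0, 1) has a direct
# statistical meaning: for continuous labels it is one minus the correlation
# between clean and noisy labels; for discrete labels it is twice the
# probability of an epoch losing its true class.

#' Add calibrated noise to continuous labels
#'
#' Produces `z_n = z + sqrt((1 - (1 - xi)^2) / (1 - xi)^2) * sd(z) * eta`,
#' with `eta` i.i.d. standard normal, so that the population correlation
#' between `z` and `z_n` equals `1 - xi` and `var(z_n) = var(z) / (1 - xi)^2`.
#' `sd(z)` is the sample standard deviation (denominator `n - 1`).
#'
#' @param z_epoch Clean continuous labels (variance must be positive).
#' @param xi Noise intensity in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical noise.
#' @return Noisy label vector of the same length.
#' @examples
#' z <- rnorm(1000)
#' zn <- add_regression_noise(z, 0.5, seed = 1)
#' cor(z, zn) # near 0.5
#' @export
add_regression_noise <- function(z_epoch, xi, seed = NULL) {
  assert_number(xi, "xi", lower = 0, upper = 1, strict_upper = TRUE)
  if (length(z_epoch) < 2L || stats::var(z_epoch) == 0)
    abort("`z_epoch` must have positive variance")
  if (xi == 0) return(z_epoch)
  scale <- sqrt((1 - (1 - xi)^2) / (1 - xi)^2) * stats::sd(z_epoch)
  eta <- run_seeded(seed, stats::rnorm(length(z_epoch)))
  z_epoch + scale * eta
}

#' Add calibrated flip noise to discrete labels
#'
#' Each epoch independently keeps its class with probability `1 - xi/2`;
#' otherwise the label is replaced by one of the remaining classes drawn
#' uniformly. Flip decisions and replacement classes come from a single
#' seeded stream in epoch order.
#'
#' @param y_epoch Integer class labels in `1:n_classes`.
#' @param xi Noise intensity in `[0, 1]`; `xi = 2 * (1 - P[y_n = y])`, so
#'   `xi = 1` keeps each label with probability one half.
#' @param n_classes Number of classes (>= 2); defaults to `max(y_epoch)`.
#' @param seed Integer seed.
#' @return Noisy label vector of the same length.
#' @export
add_classification_noise <- function(y_epoch, xi, n_classes = max(y_epoch),
                                     seed = NULL) {
  assert_number(xi, "xi", lower = 0, upper = 1)
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  if (!all(y_epoch %in% seq_len(n_classes)))
    abort("`y_epoch` must take values in 1:n_classes")
  if (xi == 0) return(y_epoch)
  n <- length(y_epoch)
  run_seeded(seed, {
    flip <- stats::runif(n) < xi / 2
    pick <- stats::runif(n) # one draw per epoch keeps the stream epoch-ordered
    y_n <- y_epoch
    if (any(flip)) {
      others <- vapply(which(flip), function(i) {
        rest <- setdiff(seq_len(n_classes), y_epoch[i])
        rest[min(length(rest), 1L + floor(pick[i] * length(rest)))]
      }, integer(1))
      y_n[flip] <- others
    }
    y_n
  })
}
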