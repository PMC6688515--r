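# CSP, shrinkage LDA, SPoC

test_that("CSP reproduces the hand-solved 2-channel eigenproblem", {
  ep1 <- epochs_with_covariance(diag(c(2, 1)), 3)
  ep2 <- epochs_with_covariance(diag(c(1, 2)), 3)
  epochs <- array(0, dim = c(6, 2, 64))
  epochs[1:3, , ] <- ep1; epochs[4:6, , ] <- ep2
  m <- fit_csp(epochs, rep(1:2, each = 3), fit_classifier = FALSE)
  # (C1 - C2) w = lambda (C1 + C2) w with the diagonals above: lambda = +-1/3
  expect_equal(sort(m$eigenvalues), c(-1 / 3, 1 / 3), tolerance = 1e-10)
  # filters are the coordinate axes, up to sign and scale
  aligned <- abs(m$W_hat) / apply(abs(m$W_hat), 2, max)
  expect_equal(aligned, cbind(c(1, 0), c(0, 1)), tolerance = 1e-8)
})

test_that("identical class covariances give vanishing eigenvalues", {
  ep <- epochs_with_covariance(diag(c(1.3, 0.8)), 4)
  epochs <- array(0, dim = c(8, 2, 64))
  epochs[1:4, , ] <- ep; epochs[5:8, , ] <- ep
  m <- fit_csp(epochs, rep(1:2, each = 4), fit_classifier = FALSE)
  expect_lt(max(abs(m$eigenvalues)), 1e-10)
})

test_that("relabeling the classes negates the spectrum, not the filters", {
  ds <- benchmark_fixture(100)
  y <- discretize_labels(ds$z_epoch, "binary")
  m1 <- fit_csp(ds$epochs, y, fit_classifier = FALSE)
  m2 <- fit_csp(ds$epochs, 3 - y, fit_classifier = FALSE)
  expect_equal(sort(m1$eigenvalues), sort(-m2$eigenvalues), tolerance = 1e-8)
  # extreme filters swap roles; compare as subspaces via |cosine|
  cosines <- abs(diag(crossprod(
    sweep(m1$W_hat, 2, sqrt(colSums(m1$W_hat^2)), "/"),
    sweep(m2$W_hat[, 2:1], 2, sqrt(colSums(m2$W_hat^2))[2:1], "/"))))
  expect_equal(unname(cosines), c(1, 1), tolerance = 1e-6)
})

test_that("the full filter set jointly diagonalizes both class covariances", {
  ds <- benchmark_fixture(100)
  y <- discretize_labels(ds$z_epoch, "binary")
  m <- fit_csp(ds$epochs, y, fit_classifier = FALSE)
  for (C in list(m$C1, m$C2)) {
    D <- crossprod(m$W_full, C) %*% m$W_full
    off <- D - diag(diag(D))
    expect_lt(max(abs(off)), 1e-8)
  }
})

test_that("CSP features are filtered-epoch variances", {
  set.seed(91)
  epochs <- array(rnorm(20 * 3 * 100), dim = c(20, 3, 100))
  model <- structure(list(W_hat = diag(3)[, 1:2], log_features = FALSE),
                     class = "csp_model")
  f <- csp_features(model, epochs)
  # naive per-epoch loop oracle
  for (e in 1:20) for (k in 1:2)
    expect_equal(f[e, k], var(epochs[e, k, ]), tolerance = 1e-12)
  # variance features scale quadratically with the signal
  f2 <- csp_features(model, epochs * 2)
  expect_equal(f2, 4 * f, tolerance = 1e-12)
  # unit-variance passthrough has log-features near zero
  flog <- csp_features(model, epochs, log = TRUE)
  expect_lt(abs(mean(flog)), 0.2)
})

test_that("shrinkage LDA separates what is separable and shrinks sanely", {
  set.seed(92)
  x <- matrix(c(rnorm(50, -1, 0.01), rnorm(50, 1, 0.01)), ncol = 1)
  y <- rep(1:2, each = 50)
  m <- fit_rlda(x, y)
  expect_equal(auc(predict(m, x), y), 1.0)
  # identical class distributions: held-out AUC hovers at chance
  aucs <- vapply(1:50, function(i) {
    xi <- matrix(rnorm(120), ncol = 2)
    yi <- rep(1:2, each = 30)
    mi <- fit_rlda(xi, yi)
    xo <- matrix(rnorm(120), ncol = 2)
    auc(predict(mi, xo), yi)
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  # full shrinkage: spherical covariance, boundary normal to the mean diff
  set.seed(93)
  x2 <- matrix(rnorm(400), ncol = 2) %*% matrix(c(2, 1.5, 0, 0.5), 2)
  x2[101:200, ] <- x2[101:200, ] + c(3, 1)
  m2 <- fit_rlda(x2, rep(1:2, each = 100), shrinkage = 1)
  md <- colMeans(x2[101:200, ]) - colMeans(x2[1:100, ])
  cosang <- sum(m2$w * md) / sqrt(sum(m2$w^2) * sum(md^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  expect_identical(m2$gamma, 1)
})

test_that("single-channel SPoC reduces to epoch variances", {
  set.seed(94)
  epochs <- array(rnorm(40 * 1 * 80), dim = c(40, 1, 80))
  z <- vapply(1:40, function(e) var(epochs[e, 1, ]), numeric(1)) + rnorm(40, 0, 0.01)
  m <- fit_spoc(epochs, z)
  expect_equal(abs(m$w), 1, tolerance = 1e-12)
  zh <- predict(m, epochs)
  for (e in 1:40) expect_equal(zh[e], var(epochs[e, 1, ]), tolerance = 1e-12)
  expect_equal(cor(zh, z), cor(vapply(1:40, function(e) var(epochs[e, 1, ]),
                                      numeric(1)), z), tolerance = 1e-12)
})

test_that("SPoC finds a channel whose power follows the target", {
  set.seed(95)
  n_ep <- 500; T <- 100
  z <- exp(rnorm(n_ep, 0, 0.5))
  epochs <- array(0, dim = c(n_ep, 2, T))
  for (e in seq_len(n_ep)) {
    epochs[e, 1, ] <- sqrt(z[e]) * rnorm(T)
    epochs[e, 2, ] <- rnorm(T)
  }
  m <- fit_spoc(epochs, z)
  expect_gte(abs(m$w[1]) / sqrt(sum(m$w^2)), 0.95)
})

test_that("the eigensolution matches an exhaustive direction search", {
  set.seed(96)
  ds <- benchmark_fixture(150)
  # 3-channel toy carved out of the benchmark data
  epochs <- ds$epochs[, 1:3, , drop = FALSE]
  z <- ds$z_epoch
  m <- fit_spoc(epochs, z)
  zs <- (z - mean(z)) / sd(z)
  # per-epoch covariances once; the objective is then a cheap quadratic form
  Ce <- lapply(seq_along(z), function(e) tcrossprod(epochs[e, , ]) / dim(epochs)[3])
  # covariance of projected power with z, normalized by the mean projected
  # power (the covariance itself grows without bound in ||w||, so the
  # maximization is over power-normalized filters)
  covobj <- function(w) {
    zh <- vapply(Ce, function(C) drop(crossprod(w, C %*% w)), numeric(1))
    mean(zs * (zh - mean(zh))) / mean(zh)
  }
  # dense search over the unit sphere (polar grid)
  best <- NULL; best_val <- -Inf
  for (th in seq(0, pi, length.out = 60)) for (ph in seq(0, 2 * pi, length.out = 120)) {
    w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    v <- covobj(w)
    if (v > best_val) { best_val <- v; best <- w }
  }
  expect_gte(abs(sum(best * m$w)), 0.99)
})

test_that("SPoC predictions scale quadratically and vanish on silence", {
  ds <- benchmark_fixture(100)
  m <- fit_spoc(ds$epochs, ds$z_epoch)
  zh <- predict(m, ds$epochs)
  expect_equal(predict(m, ds$epochs * 2), 4 * zh, tolerance = 1e-10)
  silent <- array(0, dim = c(3, dim(ds$epochs)[2], 50))
  expect_equal(predict(m, silent), rep(0, 3))
  expect_error(fit_spoc(ds$epochs, rep(1, 100)), "zero variance")
})
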