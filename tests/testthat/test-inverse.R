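# minimum-norm inverse, GCV regularization, ICA, source rescaling,
# target selection

test_that("minimum-norm estimate matches its closed form", {
  X <- matrix(rnorm(30), 3)
  # identity lead field, vanishing regularization: estimate ~ data
  est <- mne_inverse(X, diag(3), lam = 1e-12)
  expect_lt(max(abs(est$S_hat - X)), 1e-6)
  # identity lead field, lam = 1: every channel shrunk by exactly 1/2
  est2 <- mne_inverse(X, diag(3), lam = 1)
  expect_equal(est2$S_hat, X / 2, tolerance = 1e-14)
})

test_that("solve-based estimate equals the dense-inverse oracle", {
  set.seed(21)
  A <- matrix(rnorm(32), 4, 8)
  X <- matrix(rnorm(200), 4, 50)
  est <- mne_inverse(X, A, lam = 0.1)
  oracle <- t(A) %*% solve(diag(4) + 0.1 * tcrossprod(A)) %*% X
  expect_lt(max(abs(est$S_hat - oracle)) / max(abs(oracle)), 1e-10)
  # the ridge form is the plain form times lambda
  ridge <- mne_inverse(X, A, lam = 0.1, form = "ridge")
  expect_equal(ridge$S_hat, 0.1 * est$S_hat, tolerance = 1e-14)
})

test_that("the inverse operator is linear in the data", {
  set.seed(22)
  A <- matrix(rnorm(24), 4, 6)
  X1 <- matrix(rnorm(40), 4); X2 <- matrix(rnorm(40), 4)
  lhs <- mne_inverse(2 * X1 - 3 * X2, A, lam = 0.5)$S_hat
  rhs <- 2 * mne_inverse(X1, A, lam = 0.5)$S_hat -
         3 * mne_inverse(X2, A, lam = 0.5)$S_hat
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("closed form minimizes the ridge cost (generic-minimizer check)", {
  set.seed(23)
  for (i in 1:5) {
    n_c <- sample(2:5, 1); n_s <- sample(n_c:8, 1)
    A <- matrix(rnorm(n_c * n_s), n_c, n_s)
    X <- matrix(rnorm(n_c * 3), n_c, 3)
    lam <- runif(1, 0.05, 2)
    closed <- lam * mne_inverse(X, A, lam = lam)$S_hat  # minimizer of the cost
    cost <- function(v) {
      S <- matrix(v, n_s, 3)
      lam * sum((X - A %*% S)^2) + sum(S^2)
    }
    opt <- optim(rep(0, n_s * 3), cost, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(max(abs(matrix(opt$par, n_s, 3) - closed)) /
              max(abs(closed)), 1e-6)
  }
})

test_that("GCV picks heavy regularization for noise, light for structure", {
  set.seed(24)
  A <- make_leadfield(8, 8, seed = 31)$A
  grid <- 10^seq(-6, 2, length.out = 30)
  noise <- matrix(rnorm(8 * 400), 8)
  expect_equal(select_lambda_gcv(noise, A, grid), max(grid))
  clean <- A %*% matrix(rnorm(8 * 400), 8)
  expect_equal(select_lambda_gcv(clean, A, grid), min(grid))
  expect_equal(select_lambda_gcv(noise, A, 0.25), 0.25) # degenerate grid
  expect_error(select_lambda_gcv(noise, A, numeric(0)), "empty")
  expect_error(select_lambda_gcv(noise, A, c(2, 1)), "sorted")
})

test_that("auto lambda flows through mne_inverse", {
  set.seed(25)
  A <- make_leadfield(6, 6, seed = 1)$A
  X <- matrix(rnorm(6 * 200), 6)
  est <- mne_inverse(X, A, lam = "auto")
  expect_true(is.numeric(est$lambda) && est$lambda > 0)
})

test_that("ICA unmixes independent sources", {
  set.seed(26)
  S <- rbind(runif(1e5, -1, 1), runif(1e5, -1, 1))
  M <- matrix(c(1, 0.5, 0.3, 1), 2, 2)
  est <- ica_decompose(M %*% S, n_components = 2, seed = 5, fs = 1000)
  cc <- abs(cor(t(est$S_hat), t(S)))
  # best match per recovered component, up to permutation and sign
  expect_true(all(apply(cc, 1, max) > 0.99))
  # definition check: S_hat is exactly Phi X
  expect_identical(est$S_hat, est$unmixing %*% (M %*% S))
})

test_that("ICA recovers a 3-source super-Gaussian mixture", {
  set.seed(27)
  S <- rbind(rexp(5e4) * sign(rnorm(5e4)),
             rexp(5e4) * sign(rnorm(5e4)),
             rexp(5e4) * sign(rnorm(5e4)))
  M <- matrix(rnorm(9), 3, 3)
  est <- ica_decompose(M %*% S, n_components = 3, seed = 6, fs = 1000)
  cc <- abs(cor(t(est$S_hat), t(S)))
  best <- apply(cc, 1, max)
  expect_gte(mean(best), 0.95)
})

test_that("ICA is deterministic and validates its inputs", {
  set.seed(28)
  X <- matrix(rnorm(4 * 5000), 4)
  e1 <- suppressWarnings(ica_decompose(X, 4, seed = 9, fs = 1000))
  e2 <- suppressWarnings(ica_decompose(X, 4, seed = 9, fs = 1000))
  expect_identical(e1$unmixing, e2$unmixing)
  expect_warning(ica_decompose(X, 20, seed = 1, fs = 100), "clipped")
  # rank-deficient input: 4 channels spanning a 2-d space
  low <- matrix(rnorm(2 * 5000), 2)
  Xd <- rbind(low, low + 1e-13 * 0)
  expect_error(suppressWarnings(ica_decompose(Xd, 4, seed = 1, fs = 1000)),
               "rank is 2")
})

test_that("source rescaling applies the average channel covariance", {
  set.seed(29)
  # one channel equals the unit-norm source, the rest are silent:
  # the scale factor must be exactly 1/N_c
  s <- rnorm(100); s <- s / sqrt(sum(s^2))
  X <- rbind(s, matrix(0, 4, 100))
  out <- rescale_sources(matrix(s, 1), X)
  expect_equal(as.numeric(out), s / 5, tolerance = 1e-14)
  # a source orthogonal to every channel collapses to zero and is flagged
  X2 <- matrix(rep(c(1, -1), 50), 2, 100, byrow = TRUE)
  v <- rep(c(1, 1, -1, -1), 25)
  out2 <- rescale_sources(matrix(v, 1), X2)
  expect_true(all(out2 == 0))
  expect_identical(attr(out2, "flagged"), 1L)
})

test_that("rescaling matches a naive summation oracle and forgets input scale", {
  set.seed(30)
  S <- matrix(rnorm(300), 3)
  X <- matrix(rnorm(500), 5)
  out <- rescale_sources(S, X)
  for (i in 1:3) {
    u <- S[i, ] / sqrt(sum(S[i, ]^2))
    acc <- 0
    for (cch in 1:5) acc <- acc + sum(u * X[cch, ])
    expect_equal(out[i, ], (acc / 5) * u, tolerance = 1e-12)
  }
  scaled <- rescale_sources(S * 100, X)
  expect_equal(unclass(scaled), unclass(out), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("component selection policies behave as documented", {
  set.seed(31)
  t <- seq(0, 20, by = 1 / 120)
  S <- rbind(posthoclab:::one_over_f_noise(length(t), 120),
             sin(2 * pi * 10 * t),
             posthoclab:::one_over_f_noise(length(t), 120))
  expect_identical(select_component(S, "by_index", index = 3), 3L)
  expect_error(select_component(S, "by_index", index = 9), "out of range")
  expect_identical(select_component(S, "max_band_power", band_hz = c(8, 12),
                                    fs = 120), 2L)
  r1 <- select_component(S, "random", seed = 4)
  r2 <- select_component(S, "random", seed = 4)
  expect_identical(r1, r2)
})
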