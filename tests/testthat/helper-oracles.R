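# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (naive DFT, O(n^2) pair counting, exhaustive search)
# so they share no code path with the implementation they check.

# analytic signal via a naive O(n^2) DFT (independent of stats::fft)
naive_analytic_envelope <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- as.vector(Conj(W) %*% (X * h)) / n
  Mod(a)
}

# AUC by brute-force pair counting
pairwise_auc <- function(scores, y) {
  classes <- sort(unique(y))
  s_pos <- scores[y == classes[2]]
  s_neg <- scores[y == classes[1]]
  total <- 0
  for (p in s_pos) for (q in s_neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(s_pos) * length(s_neg))
}

# epochs with an exactly prescribed spatial covariance X X^T / T = C:
# rows are orthogonal sinusoids scaled to the target variances
epochs_with_covariance <- function(C, n_epochs, T = 64) {
  eg <- eigen(C, symmetric = TRUE)
  t <- seq_len(T)
  # orthogonal unit-power carriers (distinct integer frequencies)
  basis <- t(sapply(seq_len(nrow(C)), function(k) sqrt(2) * sin(2 * pi * k * t / T)))
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(C))
  ep <- array(0, dim = c(n_epochs, nrow(C), T))
  for (e in seq_len(n_epochs)) ep[e, , ] <- L %*% basis
  ep
}

# small labeled benchmark dataset, memoized so several tests can share it
benchmark_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(n_epochs = 200, seed = 42, snr_db = 0) {
    key <- paste(n_epochs, seed, snr_db, sep = "_")
    if (!exists(key, envir = cache))
      assign(key, make_benchmark_dataset(n_epochs, snr_db = snr_db, seed = seed),
             envir = cache)
    get(key, envir = cache)
  }
})
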