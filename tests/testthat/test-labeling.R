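# envelope extraction, artifact screening, epoching, discretization,
# tertiles, and the end-to-end labeling pipeline

test_that("the envelope of a constant-amplitude tone is its amplitude", {
  t <- seq(0, 10, by = 1 / 120)
  z <- extract_envelope(2 * sin(2 * pi * 10 * t))
  interior <- 61:(length(t) - 60)     # drop half a second per edge
  expect_lt(max(abs(z[interior] - 2) / 2), 0.01)
  expect_true(all(z >= 0))
  expect_identical(length(z), length(t))
})

test_that("a planted smooth modulation is recovered from the carrier", {
  t <- seq(0, 30, by = 1 / 120)
  a <- 1.5 + sin(2 * pi * 0.2 * t) * 0.8
  z <- extract_envelope(a * sin(2 * pi * 10 * t))
  interior <- 121:(length(t) - 120)
  expect_gt(cor(z[interior], a[interior]), 0.99)
})

test_that("the FFT path matches a naive-DFT analytic-signal oracle", {
  set.seed(41)
  for (n in c(64, 65)) {
    x <- rnorm(n)
    expect_lt(max(abs(extract_envelope(x) - naive_analytic_envelope(x))), 1e-10)
  }
  expect_error(extract_envelope(rnorm(4)), "8 samples")
  expect_error(extract_envelope(c(rnorm(99), NA)), "non-finite")
})

test_that("artifact rejection uses a strict peak-to-peak threshold", {
  # three 1-s windows with peak-to-peak exactly 79, 81, 200 (screening
  # filter bypassed so the threshold semantics are isolated)
  fs <- 100
  mk <- function(ptp) c(rep(0, fs / 2), rep(-ptp / 2, fs / 4), rep(ptp / 2, fs / 4))
  X <- matrix(c(mk(79), mk(81), mk(200)), 1)
  mask <- detect_artifacts(X, ptp_threshold_uv = 80, detect_band = NULL,
                           fs = fs)
  expect_identical(mask, c(FALSE, TRUE, TRUE))
  # silence is never rejected, and the mask covers whole windows only
  silent <- matrix(0, 3, 550)
  expect_identical(detect_artifacts(silent, 80, detect_band = NULL, fs = 100),
                   rep(FALSE, 5))
})

test_that("epoching truncates, removes rejections, and averages power", {
  fs <- 120
  n <- round(10.5 * fs)              # 10.5 s: trailing half window dropped
  X <- matrix(rnorm(2 * n), 2)
  z <- rep(1, n)
  ds <- epoch_and_label(X, z, window_s = 1, fs = fs)
  expect_identical(dim(ds$epochs), c(10L, 2L, 120L))
  expect_equal(ds$z_epoch, rep(1, 10))                  # constant envelope: c^2
  # alternating envelope 1, 2 per window: power labels alternate 1, 4
  z2 <- rep(rep(c(1, 2), 6)[1:10], each = fs)
  ds2 <- epoch_and_label(X[, 1:(10 * fs)], z2, window_s = 1, fs = fs)
  expect_equal(ds2$z_epoch, rep(c(1, 4), 5))
  # amplitude mode averages z itself
  ds3 <- epoch_and_label(X[, 1:(10 * fs)], z2, window_s = 1, fs = fs,
                         label_mode = "amplitude")
  expect_equal(ds3$z_epoch, rep(c(1, 2), 5))
  # rejected windows disappear from data and labels together
  mask <- rep(c(FALSE, TRUE), 5)
  ds4 <- epoch_and_label(X[, 1:(10 * fs)], z2, window_s = 1, fs = fs,
                         rejected_mask = mask)
  expect_identical(dim(ds4$epochs)[1], 5L)
  expect_equal(ds4$z_epoch, rep(1, 5))
  expect_error(epoch_and_label(X[, 1:(10 * fs)], z2, window_s = 1, fs = fs,
                               rejected_mask = rep(TRUE, 10)), "no usable")
})

test_that("percentile discretization splits as printed", {
  expect_identical(discretize_labels(1:10, "binary"), rep(1:2, each = 5))
  expect_identical(discretize_labels(1:9, "ternary"), rep(1:3, each = 3))
  # ties at the boundary fall to the lower class
  expect_identical(discretize_labels(c(1, 2, 2, 3), "binary"),
                   c(1L, 1L, 1L, 2L))
  # per-element property: permuting inputs permutes outputs identically
  set.seed(42)
  z <- rnorm(31)
  p <- sample(31)
  expect_identical(discretize_labels(z, "ternary")[p],
                   discretize_labels(z[p], "ternary"))
  expect_error(discretize_labels(rep(1, 10), "binary"), "no contrast")
  expect_error(discretize_labels(c(1, 2), "ternary"), "at least")
})

test_that("z-variance tertiles partition sources three ways", {
  sets <- lapply(1:9, function(k) list(z_epoch = sqrt(k) * rnorm(50)))
  vars <- vapply(sets, function(s) var(s$z_epoch), numeric(1))
  tert <- variance_tertiles(sets)
  expect_identical(as.character(tert[order(vars)]),
                   rep(c("low", "medium", "high"), each = 3))
  expect_identical(as.character(variance_tertiles(c(1, 2, 3))),
                   c("low", "medium", "high"))
  # a variance tied with the boundary goes to the lower tertile
  expect_identical(as.character(variance_tertiles(c(1, 1, 1, 5, 9, 9)))[1:3],
                   rep("low", 3))
  expect_warning(t2 <- variance_tertiles(c(1, 2)), "fewer than 3")
  expect_true(all(is.na(t2)))
})

test_that("the labeling pipeline is deterministic end to end", {
  src <- simulate_sources(5, 120 * 60, 120, seed = 51)
  lf <- make_leadfield(12, 5, seed = 52)
  rec <- mix_to_sensors(src, forward_spec(lf$A, noise_sd_from_snr(lf, src, 0),
                                          seed = 53))
  f1 <- posthoc_label(rec, "mne", leadfield = lf, scheme = "binary", seed = 54)
  f2 <- posthoc_label(rec, "mne", leadfield = lf, scheme = "binary", seed = 54)
  expect_identical(f1$labels$z_epoch, f2$labels$z_epoch)
  expect_identical(f1$labels$y_epoch, f2$labels$y_epoch)
  # stored metadata regenerates the labels from the raw recording alone
  f3 <- relabel(rec, f1)
  expect_identical(f3$labels$z_epoch, f1$labels$z_epoch)
  expect_identical(f3$labels$y_epoch, f1$labels$y_epoch)
  # ica path, including its seeded decomposition
  g1 <- posthoc_label(rec, "ica", n_components = 5, scheme = "ternary", seed = 55)
  g2 <- relabel(rec, g1)
  expect_identical(g1$labels$z_epoch, g2$labels$z_epoch)
  expect_identical(g1$labels$y_epoch, g2$labels$y_epoch)
})

test_that("pipeline labels track the planted source", {
  src <- simulate_sources(5, 120 * 120, 120, seed = 61)
  lf <- make_leadfield(12, 5, seed = 62)
  rec <- mix_to_sensors(src, forward_spec(lf$A, noise_sd_from_snr(lf, src, 0),
                                          seed = 63))
  fit <- posthoc_label(rec, "mne", leadfield = lf, seed = 64)
  envb <- extract_envelope(bandpass(src$S[1, ], 8, 12, fs = 120))
  fs <- 120
  zp <- vapply(fit$epochs$kept, function(w)
    mean(envb[((w - 1) * fs + 1):(w * fs)]^2), numeric(1))
  expect_gt(cor(fit$labels$z_epoch, zp), 0.9)
})

test_that("labels are scale-equivariant in the recording", {
  src <- simulate_sources(4, 120 * 40, 120, seed = 71)
  lf <- make_leadfield(10, 4, seed = 72)
  rec <- mix_to_sensors(src, forward_spec(lf$A, noise_sd_from_snr(lf, src, 0),
                                          seed = 73))
  rec2 <- rec; rec2$X <- 3 * rec$X
  f1 <- posthoc_label(rec, "mne", leadfield = lf, scheme = "binary",
                      ptp_reject = Inf, lam = 0.5, seed = 74)
  f2 <- posthoc_label(rec2, "mne", leadfield = lf, scheme = "binary",
                      ptp_reject = Inf, lam = 0.5, seed = 74)
  expect_equal(f2$labels$z_cont, 3 * f1$labels$z_cont, tolerance = 1e-10)
  expect_identical(f2$labels$y_epoch, f1$labels$y_epoch)
})
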