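# Benchmarking harness: chronological cross-validation, single-cell
# evaluation with training-label corruption, and the factorial sweep over
# label variability (tertiles), dataset size, and label noise.

#' Chronological k-fold partition
#'
#' Splits `n_epochs` temporally ordered epochs into `k` contiguous blocks
#' (sizes differing by at most one, earliest blocks largest); fold `i` tests
#' on block `i` and trains on the remaining blocks. Contiguous blocks avoid
#' the temporal leakage that shuffled cross-validation induces in
#' autocorrelated neurophysiological data.
#'
#' @param n_epochs Number of epochs (>= `2 * k`).
#' @param k Number of folds.
#' @return List of `k` elements, each `list(train =, test =)` index vectors.
#' @examples
#' chronological_kfold(10, 5)
#' @export
chronological_kfold <- function(n_epochs, k = 5) {
  n_epochs <- assert_count(n_epochs, "n_epochs")
  k <- assert_count(k, "k", min = 2L)
  if (n_epochs < 2 * k)
    abort(sprintf("need at least %d epochs for %d folds", 2 * k, k))
  sizes <- rep(n_epochs %/% k, k)
  rem <- n_epochs %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    test <- starts[i]:ends[i]
    list(train = setdiff(seq_len(n_epochs), test), test = test)
  })
}

# ---- decoder plug-in registry ------------------------------------------------

decoder_registry <- new.env(parent = emptyenv())

#' Register a decoder for benchmark sweeps
#'
#' A decoder is a pair of functions: `fit(epochs, labels)` returning a model,
#' and `predict(model, epochs)` returning continuous scores (binary), class
#' labels (ternary) or label estimates (regression). External methods (e.g. a
#' user-supplied neural network) participate in sweeps through this contract.
#'
#' @param name Decoder name.
#' @param fit,predict The fit/predict pair.
#' @param schemes Label schemes the decoder supports.
#' @export
register_decoder <- function(name, fit, predict,
                             schemes = c("binary", "ternary", "regression")) {
  assign(name, list(fit = fit, predict = predict, schemes = schemes),
         envir = decoder_registry)
  invisible(name)
}

get_decoder <- function(name) {
  if (is.list(name) && all(c("fit", "predict") %in% names(name))) return(name)
  if (!exists(name, envir = decoder_registry))
    abort(sprintf("unknown decoder '%s'", name))
  get(name, envir = decoder_registry)
}

register_builtin_decoders <- function() {
  register_decoder("csp",
    fit = function(epochs, labels) fit_csp(epochs, labels),
    predict = function(model, epochs) predict(model, epochs),
    schemes = "binary")
  register_decoder("spoc",
    fit = function(epochs, labels) fit_spoc(epochs, labels),
    predict = function(model, epochs) predict(model, epochs),
    schemes = "regression")
}

# ---- single sweep cell -------------------------------------------------------

#' Evaluate one benchmark cell
#'
#' Takes the chronologically first `n_epochs` epochs of a labeled dataset,
#' corrupts the *training* labels with noise of intensity `xi` (test labels
#' stay clean: the noise models corrupted supervision, while evaluation is
#' against ground truth), and runs chronological k-fold cross-validation of
#' the decoder. The metric is AUC for binary labels, accuracy for ternary,
#' and Pearson correlation for regression.
#'
#' @param dataset A list with `epochs` (3-d array) and `z_epoch` (clean
#'   continuous labels), e.g. from [make_benchmark_dataset()] or a
#'   `posthoc_labels` object.
#' @param decoder Registered decoder name (`"csp"`, `"spoc"`) or a
#'   fit/predict pair (see [register_decoder()]).
#' @param n_epochs Number of epochs to use (must be available).
#' @param xi Label-noise intensity in `[0, 1)`.
#' @param scheme `"binary"`, `"ternary"` or `"regression"`.
#' @param n_folds Number of chronological folds.
#' @param seed Seed for the label-noise stream.
#' @param noisy_test Also corrupt the test labels (off by default).
#' @return List with `metric`, `mean`, `sd`, `per_fold`, `folds_used`.
#' @export
evaluate_cell <- function(dataset, decoder, n_epochs, xi = 0,
                          scheme = c("binary", "ternary", "regression"),
                          n_folds = 5, seed = NULL, noisy_test = FALSE) {
  scheme <- match.arg(scheme)
  if (inherits(dataset, "posthoc_labels"))
    dataset <- list(epochs = dataset$epochs$epochs,
                    z_epoch = dataset$labels$z_epoch)
  epochs <- epoch_array(dataset$epochs)
  avail <- dim(epochs)[1]
  n_epochs <- assert_count(n_epochs, "n_epochs")
  if (n_epochs > avail)
    abort(sprintf("requested %d epochs but only %d are available", n_epochs, avail))
  dec <- get_decoder(decoder)
  if (!scheme %in% dec$schemes)
    abort(sprintf("decoder does not support the '%s' scheme", scheme))

  idx <- seq_len(n_epochs)
  ep <- epochs[idx, , , drop = FALSE]
  z <- dataset$z_epoch[idx]
  labels <- switch(scheme,
    regression = z,
    binary = discretize_labels(z, "binary"),
    ternary = discretize_labels(z, "ternary"))
  n_classes <- switch(scheme, binary = 2L, ternary = 3L, regression = NA_integer_)

  noisy <- if (xi == 0) labels
           else if (scheme == "regression") add_regression_noise(labels, xi, seed)
           else add_classification_noise(labels, xi, n_classes, seed)

  folds <- chronological_kfold(n_epochs, n_folds)
  metric_name <- switch(scheme, binary = "auc", ternary = "accuracy",
                        regression = "pearson")
  per_fold <- vapply(folds, function(f) {
    y_tr <- noisy[f$train]
    y_te <- if (noisy_test) noisy[f$test] else labels[f$test]
    if (scheme != "regression" && length(unique(y_tr)) < n_classes)
      return(NA_real_)           # degenerate fold, flagged as NA
    model <- dec$fit(ep[f$train, , , drop = FALSE], y_tr)
    pred <- dec$predict(model, ep[f$test, , , drop = FALSE])
    switch(metric_name,
           auc = auc(pred, y_te),
           accuracy = accuracy(pred, y_te),
           pearson = pearson(pred, y_te))
  }, numeric(1))
  used <- sum(!is.na(per_fold))
  list(metric = metric_name,
       mean = mean(per_fold, na.rm = TRUE),
       sd = stats::sd(per_fold[!is.na(per_fold)]),
       per_fold = per_fold, folds_used = used)
}

# ---- full sweep --------------------------------------------------------------

#' Sweep configuration
#'
#' @param decoder Decoder name.
#' @param epoch_counts Dataset sizes to sweep (each >= `2 * n_folds`).
#' @param noise_grid Label-noise intensities in `[0, 1)`.
#' @param tertiles Label-variability groups to evaluate.
#' @param n_folds Chronological folds per cell.
#' @param seeds One sweep repetition per seed.
#' @param scheme Label scheme.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(decoder = "csp",
                         epoch_counts = c(50, 100, 250, 500, 1000, 2000),
                         noise_grid = seq(0, 0.8, by = 0.05),
                         tertiles = c("low", "medium", "high"),
                         n_folds = 5, seeds = 1L,
                         scheme = c("binary", "ternary", "regression")) {
  scheme <- match.arg(scheme)
  if (any(epoch_counts < 2 * n_folds))
    abort("every epoch count must be at least 2 * n_folds")
  if (any(noise_grid < 0 | noise_grid >= 1))
    abort("noise intensities must lie in [0, 1)")
  structure(list(decoder = decoder, epoch_counts = epoch_counts,
                 noise_grid = noise_grid, tertiles = tertiles,
                 n_folds = n_folds, seeds = seeds, scheme = scheme),
            class = "sweep_config")
}

cell_key <- function(cell) {
  json <- jsonlite::toJSON(cell, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full benchmark sweep
#'
#' Evaluates the full factorial grid tertile x dataset size x noise x seed
#' for one decoder, returning one long-format record per cross-validation
#' fold. Cells already present in `cache_dir` (keyed by a hash of their
#' configuration) are reloaded rather than recomputed, making long sweeps
#' resumable.
#'
#' @param config A [sweep_config()].
#' @param datasets Named list of labeled datasets keyed by tertile (each with
#'   `epochs` and `z_epoch`).
#' @param cache_dir Optional directory for per-cell result caching.
#' @return A `sweep_result` data frame with columns `decoder`, `tertile`,
#'   `n_epochs`, `xi`, `seed`, `fold`, `metric_name`, `metric_value`.
#' @export
run_sweep <- function(config, datasets, cache_dir = NULL) {
  if (!inherits(config, "sweep_config")) abort("`config` must be a sweep_config")
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (tert in config$tertiles) {
    if (!tert %in% names(datasets)) {
      warning(sprintf("no dataset for tertile '%s'; skipped", tert))
      next
    }
    for (n_ep in config$epoch_counts) for (xi in config$noise_grid)
      for (sd_ in config$seeds) {
        cell <- list(decoder = config$decoder, tertile = tert, n_epochs = n_ep,
                     xi = xi, seed = sd_, scheme = config$scheme,
                     n_folds = config$n_folds)
        res <- NULL
        cache_file <- if (!is.null(cache_dir))
          file.path(cache_dir, paste0(cell_key(cell), ".rds"))
        if (!is.null(cache_file) && file.exists(cache_file))
          res <- readRDS(cache_file)
        if (is.null(res)) {
          res <- evaluate_cell(datasets[[tert]], config$decoder, n_ep, xi,
                               config$scheme, config$n_folds, seed = sd_)
          if (!is.null(cache_file)) saveRDS(res, cache_file)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          decoder = config$decoder, tertile = tert, n_epochs = n_ep, xi = xi,
          seed = sd_, fold = seq_along(res$per_fold),
          metric_name = res$metric, metric_value = res$per_fold,
          stringsAsFactors = FALSE)
      }
  }
  out <- if (length(rows) == 0L)
    data.frame(decoder = character(), tertile = character(),
               n_epochs = integer(), xi = numeric(), seed = integer(),
               fold = integer(), metric_name = character(),
               metric_value = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d records: %s, metric %s\n",
              nrow(x), paste(unique(x$decoder), collapse = ", "),
              paste(unique(x$metric_name), collapse = ", ")))
  NextMethod()
}

#' @export
summary.sweep_result <- function(object, ...) {
  agg <- stats::aggregate(metric_value ~ decoder + tertile + n_epochs + xi,
                          data = object, FUN = function(v)
                            c(mean = mean(v, na.rm = TRUE),
                              sd = stats::sd(v[!is.na(v)])))
  out <- cbind(agg[, 1:4], agg$metric_value)
  names(out)[5:6] <- c("mean", "sd")
  out
}

#' @export
plot.sweep_result <- function(x, by = c("xi", "n_epochs"), ...) {
  by <- match.arg(by)
  agg <- stats::aggregate(list(metric_value = x$metric_value),
                          by = list(tertile = x$tertile, v = x[[by]]),
                          FUN = mean, na.rm = TRUE)
  names(agg)[2] <- by
  terts <- unique(agg$tertile)
  cols <- seq_along(terts)
  graphics::plot(range(agg[[by]]), range(agg$metric_value), type = "n",
                 xlab = by, ylab = unique(x$metric_name)[1],
                 main = sprintf("%s vs %s", unique(x$metric_name)[1], by), ...)
  for (i in seq_along(terts)) {
    sub <- agg[agg$tertile == terts[i], ]
    graphics::lines(sub[[by]], sub$metric_value, col = cols[i], type = "b", pch = 19)
  }
  graphics::legend("bottomleft", legend = terts, col = cols, lty = 1, pch = 19)
  invisible(x)
}

# ---- ready-made benchmark dataset -------------------------------------------

#' Generate a ground-truth labeled benchmark dataset
#'
#' Convenience wrapper around the forward simulator and the epoching step: a
#' planted narrowband target source among 1/f background sources is mixed to
#' the sensors at a requested broadband SNR, the sensor data are bandpassed
#' to the target band, and the planted envelope (known exactly) provides the
#' clean epoch labels. The planted spatial pattern is returned for
#' parameter-recovery checks.
#'
#' @param n_epochs Number of 1-window epochs to generate.
#' @param n_channels Number of sensors.
#' @param n_background Number of 1/f background sources.
#' @param fs Sampling rate in Hz.
#' @param band Target band in Hz.
#' @param window_s Epoch length in seconds.
#' @param snr_db Broadband sensor SNR in dB.
#' @param envelope_timescale_s Envelope fluctuation timescale in seconds.
#' @param seed Integer seed (sub-seeds are derived for each stage).
#' @return List with `epochs`, `z_epoch`, `pattern` (planted, unit norm),
#'   `A`, `recording`, `sources`, `meta`.
#' @export
make_benchmark_dataset <- function(n_epochs, n_channels = 20, n_background = 10,
                                   fs = 120, band = c(8, 12), window_s = 1,
                                   snr_db = 0, envelope_timescale_s = 2,
                                   seed = 1L) {
  seed <- assert_count(seed, "seed", min = 0L)
  n_sources <- n_background + 1L
  n_samples <- n_epochs * round(fs * window_s)
  src <- simulate_sources(n_sources, n_samples, fs, band,
                          envelope_timescale_s, seed = seed)
  lf <- make_leadfield(n_channels, n_sources, seed = seed + 1L)
  sd_noise <- noise_sd_from_snr(lf$A, src$S, snr_db)
  spec <- forward_spec(lf$A, sd_noise, seed = seed + 2L)
  rec <- mix_to_sensors(src, spec)
  Xb <- bandpass(rec, band[1], band[2])
  env_band <- extract_envelope(bandpass(src$S[src$target_index, ],
                                        band[1], band[2], fs = fs))
  ds <- epoch_and_label(Xb, env_band, window_s)
  pat <- lf$A[, src$target_index]
  list(epochs = ds$epochs, z_epoch = ds$z_epoch,
       pattern = pat / sqrt(sum(pat^2)), A = lf$A,
       recording = rec, sources = src,
       meta = list(n_channels = n_channels, n_background = n_background,
                   fs = fs, band = band, snr_db = snr_db, seed = seed))
}
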