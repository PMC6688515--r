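# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    abort(sprintf("`%s` = %g is outside the admissible range", name, x))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix", name))
  if (!all(is.finite(x)))
    abort(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}

#' @importFrom withr with_seed
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- assert_count(seed, "seed", min = 0L)
  withr::with_seed(seed, expr)
}

# quantile with linear interpolation (type 7); ties at a boundary fall to the
# lower bin throughout the package
lower_tie_cut <- function(x, breaks) {
  out <- rep_len(1L, length(x))
  for (b in breaks) out <- out + (x > b)
  as.integer(out)
}
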