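# Plain-text dataset layout: delimited matrices plus a JSON metadata file.
# Portable, diff-able, and readable from any environment.

#' Write a labeled dataset to a plain-text directory layout
#'
#' Serializes epochs (flattened to a samples-in-columns table), continuous
#' and discrete labels, and a JSON metadata record (dimensions, band, scheme,
#' seeds) into `dir`.
#'
#' @param x A `posthoc_labels` object or a list with `epochs` (3-d array) and
#'   `z_epoch`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_labeled_dataset <- function(x, dir) {
  if (inherits(x, "posthoc_labels"))
    x <- list(epochs = x$epochs$epochs, z_epoch = x$labels$z_epoch,
              y_epoch = x$labels$y_epoch, meta = x$meta)
  epochs <- epoch_array(x$epochs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(epochs)
  flat <- matrix(aperm(epochs, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE),
                     file.path(dir, "epochs.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(format(x$z_epoch, digits = 17, trim = TRUE),
             file.path(dir, "labels_z.txt"))
  if (!is.null(x$y_epoch))
    writeLines(as.character(x$y_epoch), file.path(dir, "labels_y.txt"))
  meta <- c(list(dim = d), x$meta %||% list())
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a labeled dataset written by [write_labeled_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `epochs`, `z_epoch`, optional `y_epoch`, and `meta`.
#' @export
read_labeled_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  flat <- as.matrix(utils::read.table(file.path(dir, "epochs.tsv"), sep = "\t"))
  epochs <- aperm(array(t(flat), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  z <- as.numeric(readLines(file.path(dir, "labels_z.txt")))
  y_path <- file.path(dir, "labels_y.txt")
  y <- if (file.exists(y_path)) as.integer(readLines(y_path)) else NULL
  meta$dim <- NULL
  list(epochs = epochs, z_epoch = z, y_epoch = y, meta = meta)
}
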