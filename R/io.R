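# File interfaces: masks as 8-bit PNG (0 background / 255 foreground),
# feature tables and labels as CSV.

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1.0, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Any pixel above half intensity is foreground; RGB(A) images are reduced
#' to their first channel.
#'
#' @param path PNG file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' Write a mask collection plus labels to a directory
#'
#' Masks go to `<dir>/<id>.png`; labels to `<dir>/labels.csv` with columns
#' `id,label` (regular = 1, irregular = 0).
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(dataset$masks))
    write_mask(dataset$masks[[i]], file.path(dir, paste0(dataset$ids[i], ".png")))
  utils::write.csv(data.frame(id = dataset$ids, label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read an irregularity feature table
#'
#' CSV with columns `id,fractal_dimension,convexity[,label]`.
#'
#' @param features data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
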