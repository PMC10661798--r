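# File interfaces: 16-bit label TIFFs, multi-page grayscale stacks,
# and the CSV point/measurement tables.

#' Write a label image as a single-plane unsigned 16-bit TIFF
#'
#' Background is 0, cells are 1..n (n must be <= 65535).
#'
#' @param label integer matrix.
#' @param path output path.
#' @export
write_label_tiff <- function(label, path) {
  label <- as.matrix(label)
  if (max(label) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(label / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label image written by [write_label_tiff()]
#'
#' @param path TIFF path.
#' @return integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}

#' Write a grayscale frame stack as a multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale; values are clamped to
#' `[0, 1]`.
#'
#' @param frames list of numeric matrices.
#' @param path output path.
#' @export
write_stack_tiff <- function(frames, path) {
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale frame stack from a multi-page TIFF
#'
#' @param path TIFF path.
#' @return list of numeric matrices in `[0, 1]`.
#' @export
read_stack_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  lapply(img, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]
    f
  })
}

#' Write a point table (`cell_id, x, y, kind`)
#' @param points data frame.
#' @param path CSV path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Read a point table written by [write_points_csv()]
#' @param path CSV path.
#' @export
read_points_csv <- function(path) {
  p <- utils::read.csv(path)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(p))) {
    stop("point table ", path, " must have columns cell_id, x, y")
  }
  p
}
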