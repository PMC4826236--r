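#' Single-channel raster image with bit-depth metadata
#'
#' An `image_grid` is an integer matrix of pixel intensities together with
#' the acquisition bit depth (8 or 16). Pixel coordinates are (row, col),
#' 0-based in all exported coordinate tables, origin at the top-left.
#'
#' @param values numeric matrix of non-negative integer intensities.
#' @param bit_depth integer, 8 or 16. All values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `image_grid`: an integer matrix with a
#'   `bit_depth` attribute.
#' @examples
#' img <- image_grid(matrix(0:255, 16, 16), bit_depth = 8)
#' dim(img)
#' @export
image_grid <- function(values, bit_depth = 8L) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("image must be non-empty")
  v <- as.vector(values)
  if (anyNA(v)) stop("image values must not be NA")
  if (any(v < 0) || any(v > 2^bit_depth - 1)) {
    stop("values outside [0, 2^bit_depth - 1]")
  }
  if (any(v != round(v))) stop("image values must be integers")
  storage.mode(values) <- "integer"
  structure(values, bit_depth = bit_depth, class = c("image_grid", "matrix"))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, %d-bit, range [%d, %d]\n",
              nrow(x), ncol(x), bit_depth(x), min(x), max(x)))
  invisible(x)
}

#' Bit depth of an image
#' @param image an `image_grid`.
#' @return Integer bit depth (8 or 16).
#' @export
bit_depth <- function(image) {
  bd <- attr(image, "bit_depth")
  if (is.null(bd)) 8L else as.integer(bd)
}

#' Strip image class, keeping the bare integer matrix
#' @param x an `image_grid` or `label_mask`.
#' @param ... unused.
#' @return A plain integer matrix.
#' @export
as_matrix <- function(x, ...) {
  attr(x, "bit_depth") <- NULL
  class(x) <- NULL
  x
}

#' Integer-labelled segmentation mask
#'
#' Label 0 is background; objects are labelled 1..K. `label_mask()`
#' optionally compacts the label set so it has no gaps.
#'
#' @param labels matrix of non-negative integers.
#' @param compact logical; relabel objects as 1..K in order of first
#'   appearance of the original labels (default `TRUE`).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, compact = TRUE) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  v <- as.vector(labels)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  if (compact) {
    ids <- sort(unique(v[v > 0]))
    if (length(ids) > 0L && !identical(as.integer(ids), seq_along(ids))) {
      remap <- integer(max(ids))
      remap[ids] <- seq_along(ids)
      pos <- labels > 0L
      labels[pos] <- remap[labels[pos]]
    }
  }
  structure(labels, class = c("label_mask", "matrix"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, %d object(s)\n",
              nrow(x), ncol(x), n_labels(x)))
  invisible(x)
}

#' Number of labelled objects in a mask
#' @param mask a `label_mask`.
#' @return Integer count of distinct non-zero labels.
#' @export
n_labels <- function(mask) {
  length(unique(mask[mask > 0L]))
}

stopifnot_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("%s must share dimensions (%s vs %s)", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")))
  }
  invisible(TRUE)
}
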