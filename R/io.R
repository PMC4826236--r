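#' Read one channel of a TIFF or PNG image
#'
#' Reads greyscale or multichannel TIFF (preferred) and PNG files and
#' returns a single channel as an [image_grid]. Bit depth is inferred from
#' the file: TIFF from its `bits.per.sample` tag, PNG from whether the
#' decoded intensities are expressible on the 8-bit scale.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param channel_index 1-based channel to extract (default 1).
#' @return An [image_grid] holding the requested channel.
#' @seealso [write_image()] for the inverse operation.
#' @export
read_image <- function(path, channel_index = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  channel_index <- as.integer(channel_index)
  if (ext %in% c("tif", "tiff")) {
    raw <- withCallingHandlers(
      tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
               error = function(e) stop(sprintf("cannot read '%s': %s",
                                                path, conditionMessage(e)))),
      # libtiff flags non-RGB sample counts (e.g. 2-channel stacks) as
      # ExtraSamples; the pixels decode fine
      warning = function(w) {
        if (grepl("ExtraSamples", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
    vals <- extract_channel(unclass(raw), channel_index)
    # multi-sample TIFFs decode to [0, 1] even with as.is; rescale back
    if (any(vals != round(vals))) vals <- round(vals * (2^as.integer(bits) - 1))
    image_grid(vals, bit_depth = as.integer(bits))
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) stop(sprintf("cannot read '%s': %s",
                                                     path, conditionMessage(e))))
    v16 <- round(extract_channel(raw, channel_index) * 65535)
    if (all(v16 %% 257 == 0)) {
      image_grid(v16 / 257, bit_depth = 8L)
    } else {
      image_grid(v16, bit_depth = 16L)
    }
  } else {
    stop(sprintf("unsupported image format: '%s'", ext))
  }
}

extract_channel <- function(arr, channel_index) {
  d <- dim(arr)
  ch <- if (length(d) == 2L || is.null(d)) {
    if (channel_index != 1L) stop("channel_index out of range: image has 1 channel")
    arr
  } else {
    if (channel_index < 1L || channel_index > d[3]) {
      stop(sprintf("channel_index out of range: image has %d channel(s)", d[3]))
    }
    arr[, , channel_index]
  }
  # strip decoder metadata attributes; keep the bare pixel grid
  matrix(as.vector(ch), nrow(ch), ncol(ch))
}

#' Write an image (or a set of channels) to TIFF
#'
#' @param image an [image_grid], or a named list of same-sized
#'   `image_grid`s written as one multichannel TIFF.
#' @param path output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "image_grid")) image <- list(image)
  bd <- bit_depth(image[[1]])
  top <- 2^bd - 1
  mats <- lapply(image, function(ch) as_matrix(ch) / top)
  arr <- if (length(mats) == 1L) {
    mats[[1]]
  } else {
    array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  }
  ok <- tryCatch(tiff::writeTIFF(arr, path, bits.per.sample = bd),
                 error = function(e) stop(sprintf("cannot write '%s': %s",
                                                  path, conditionMessage(e))))
  invisible(path)
}

#' Rescale an image to 8-bit
#'
#' Linear min-max rescale of the observed intensity range onto
#' `[0, 255]` with round-half-up. An 8-bit input is returned unchanged; a
#' constant input maps to the constant 0 image by convention. Supplying
#' `range` rescales a fixed intensity window instead of the observed
#' extremes (values outside the window are clipped), which makes the
#' conversion comparable across images.
#'
#' @param image an [image_grid].
#' @param range optional length-2 numeric, a fixed `(low, high)` window.
#' @return An 8-bit [image_grid].
#' @export
to_8bit <- function(image, range = NULL) {
  if (is.null(range) && bit_depth(image) == 8L) return(image)
  v <- as.numeric(as_matrix(image))
  if (is.null(range)) {
    lo <- min(v); hi <- max(v)
  } else {
    stopifnot(length(range) == 2L, range[1] < range[2])
    lo <- range[1]; hi <- range[2]
    v <- pmin(pmax(v, lo), hi)
  }
  out <- if (hi == lo) rep(0, length(v)) else round_half_up((v - lo) / (hi - lo) * 255)
  image_grid(matrix(out, nrow(image), ncol(image)), bit_depth = 8L)
}

#' Write a results table as CSV
#'
#' Writes records with a fixed, documented column order (the column order
#' of `rows`) as UTF-8, comma-separated CSV with a `.` decimal mark and
#' full floating-point precision. An empty table yields a header-only file.
#'
#' @param rows a data.frame of records sharing one schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame")
  ok <- tryCatch(utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                                  fileEncoding = "UTF-8"),
                 error = function(e) stop(sprintf("cannot write '%s': %s",
                                                  path, conditionMessage(e))))
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path path to a CSV file.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Column order of the per-nucleus texture table
#'
#' The fixed schema used by [write_table()] for per-nucleus texture
#' records produced by the pipeline.
#' @return Character vector of column names.
#' @export
texture_table_columns <- function() {
  c("sample_id", "group", "nucleus_id", "area_px",
    "asm", "contrast", "correlation", "idm", "entropy",
    "correlation_defined")
}
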