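#' Greyscale image container
#'
#' A `grey_image` is an integer matrix of pixel intensities with a declared
#' number of quantized grey levels `L`. Pixel values run from 0 (black) to
#' `L - 1` (white); the default `L = 256` matches 8-bit B-mode ultrasound
#' frames. Row 1 is the top of the image (shallowest depth), so increasing
#' row index corresponds to increasing imaging depth.
#'
#' @param pixels Integer matrix (rows x columns) of grey values.
#' @param levels Number of quantized grey levels `L` (default 256).
#' @param source_id Free-text provenance tag (file path, phantom id, ...).
#'
#' @return An object of class `grey_image`: the pixel matrix with
#'   attributes `levels` and `source_id`.
#' @export
#' @examples
#' img <- grey_image(matrix(0:3, 2, 2), levels = 4)
#' n_levels(img)
grey_image <- function(pixels, levels = 256L, source_id = "") {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix of grey values", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) {
    stop("`levels` must be an integer >= 2", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite and non-missing", call. = FALSE)
  }
  if (any(pixels != round(pixels))) {
    stop("pixel values must be integers (quantized grey levels)", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > levels - 1L)) {
    stop("pixel values must lie in [0, levels - 1]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels,
    levels = levels, source_id = as.character(source_id)[1],
    class = c("grey_image", "matrix", "array")
  )
}

#' @rdname grey_image
#' @param x A `grey_image`.
#' @export
n_levels <- function(x) attr(x, "levels")

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf(
    "<grey_image> %d x %d pixels, L = %d, range [%d, %d]%s\n",
    nrow(x), ncol(x), n_levels(x), min(x), max(x),
    if (nzchar(attr(x, "source_id"))) paste0(", source: ", attr(x, "source_id")) else ""
  ))
  invisible(x)
}

#' Crop a rectangular region of interest
#'
#' Extracts an axis-aligned rectangle from a greyscale image. Coordinates
#' are 0-based `(row, column)` with the origin at the top-left pixel, so
#' `top = 0, left = 0` starts at the first pixel. The rectangle must lie
#' wholly inside the image: no clamping is performed.
#'
#' @param image A [grey_image()].
#' @param top,left 0-based row/column of the rectangle's top-left corner.
#' @param height,width Extent of the rectangle in pixels (each >= 1).
#'
#' @return A `grey_image` of exactly `height x width` pixels with the same
#'   grey-level count as the input.
#' @export
#' @examples
#' img <- grey_image(matrix(0:15, 4, 4, byrow = TRUE), levels = 16)
#' crop_roi(img, 0, 0, 2, 4) # top two rows
crop_roi <- function(image, top, left, height, width) {
  stopifnot(inherits(image, "grey_image"))
  top <- as.integer(top); left <- as.integer(left)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) {
    stop("crop height and width must be >= 1", call. = FALSE)
  }
  if (top < 0L || left < 0L ||
      top + height > nrow(image) || left + width > ncol(image)) {
    stop(sprintf(
      "crop rectangle (top=%d, left=%d, height=%d, width=%d) exceeds the %d x %d image",
      top, left, height, width, nrow(image), ncol(image)
    ), call. = FALSE)
  }
  px <- unclass(image)[top + seq_len(height), left + seq_len(width), drop = FALSE]
  grey_image(px, levels = n_levels(image), source_id = attr(image, "source_id"))
}
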