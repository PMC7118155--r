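#' Read a greyscale image from disk
#'
#' Loads PNG, TIFF, PGM (8-bit, ASCII `P2` or binary `P5`) or CSV integer
#' matrices into a [grey_image()]. RGB inputs are converted to grey with the
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114) and rounded; an alpha
#' channel, if present, is ignored. 8-bit image formats are kept at their
#' native 256-level quantization when `levels = 256`; requesting fewer
#' levels requantizes by `floor(v * levels / 256)`. CSV matrices are taken
#' as already quantized to the declared `levels` and are validated, not
#' rescaled.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.pgm` or `.csv` file.
#' @param levels Grey-level count `L` of the result (default 256).
#'
#' @return A [grey_image()] whose `source_id` records `path`.
#' @export
read_grey_image <- function(path, levels = 256L) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = read_raster_8bit(png::readPNG(path), path),
    tif = ,
    tiff = {
      frames <- tiff::readTIFF(path, all = TRUE)
      if (length(frames) > 1L) {
        stop(sprintf("'%s' is a multi-frame image; supply single-frame inputs", path),
          call. = FALSE)
      }
      read_raster_8bit(frames[[1]], path)
    },
    pgm = read_pgm(path),
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(m) <- NULL
      if (anyNA(m)) stop(sprintf("'%s' contains non-numeric cells", path), call. = FALSE)
      return(grey_image(m, levels = levels, source_id = path))
    },
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path), call. = FALSE)
  )
  levels <- as.integer(levels)
  if (levels < 256L) px <- floor(px * (levels / 256))
  px <- pmin(pmax(px, 0L), levels - 1L)
  grey_image(px, levels = levels, source_id = path)
}

# Convert a decoded raster array ([0,1] doubles from png/tiff) to an
# integer 0..255 matrix; RGB collapsed by BT.601 luma, alpha dropped.
read_raster_8bit <- function(arr, path) {
  if (length(dim(arr)) == 2L) {
    return(round(arr * 255))
  }
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    reshape <- function(v) matrix(v, dim(arr)[1], dim(arr)[2])
    if (nc == 2L) return(reshape(round(arr[, , 1] * 255))) # grey + alpha
    if (nc %in% c(3L, 4L)) {
      r <- round(arr[, , 1] * 255)
      g <- round(arr[, , 2] * 255)
      b <- round(arr[, , 3] * 255)
      return(reshape(round(0.299 * r + 0.587 * g + 0.114 * b)))
    }
  }
  stop(sprintf("'%s' is neither single-channel nor RGB", path), call. = FALSE)
}

# Minimal 8-bit PGM reader (P2 ASCII / P5 binary), maxval <= 255.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  # header tokens: magic, width, height, maxval (comments start with '#')
  header_tokens <- character(0)
  i <- 1L
  n <- length(raw_all)
  while (length(header_tokens) < 4L && i <= n) {
    ch <- rawToChar(raw_all[i])
    if (ch == "#") { # comment to end of line
      while (i <= n && !rawToChar(raw_all[i]) %in% c("\n", "\r")) i <- i + 1L
    } else if (grepl("^[[:space:]]$", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[[:space:]]$", rawToChar(raw_all[j])) &&
             rawToChar(raw_all[j]) != "#") j <- j + 1L
      header_tokens <- c(header_tokens, rawToChar(raw_all[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(header_tokens) < 4L || !header_tokens[1] %in% c("P2", "P5")) {
    stop(sprintf("'%s' is not an 8-bit PGM (P2/P5) file", path), call. = FALSE)
  }
  width <- as.integer(header_tokens[2])
  height <- as.integer(header_tokens[3])
  maxval <- as.integer(header_tokens[4])
  if (is.na(width) || is.na(height) || is.na(maxval) || maxval > 255L) {
    stop(sprintf("'%s': unsupported PGM header (only 8-bit supported)", path),
      call. = FALSE)
  }
  if (header_tokens[1] == "P5") {
    i <- i + 1L # single whitespace byte after maxval
    vals <- as.integer(raw_all[i:(i + width * height - 1L)])
  } else {
    body <- rawToChar(raw_all[i:n])
    vals <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])
  }
  if (length(vals) != width * height || anyNA(vals)) {
    stop(sprintf("'%s': PGM pixel data does not match header dimensions", path),
      call. = FALSE)
  }
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a greyscale image to disk
#'
#' The format follows the file extension: `.png` (8-bit grey PNG), `.pgm`
#' (ASCII `P2`), or `.csv` (plain integer matrix). PNG and PGM require
#' `levels <= 256`. Lossless round-trips preserve every pixel exactly.
#'
#' @param image A [grey_image()].
#' @param path Output path ending in `.png`, `.pgm` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(image, path) {
  stopifnot(inherits(image, "grey_image"))
  ext <- tolower(tools::file_ext(path))
  px <- unclass(image)
  attr(px, "levels") <- NULL
  attr(px, "source_id") <- NULL
  if (ext %in% c("png", "pgm") && n_levels(image) > 256L) {
    stop("PNG/PGM export supports at most 256 grey levels", call. = FALSE)
  }
  switch(ext,
    png = png::writePNG(px / 255, target = path),
    pgm = {
      lines <- c(
        "P2", paste(ncol(px), nrow(px)), "255",
        apply(px, 1L, paste, collapse = " ")
      )
      writeLines(lines, path)
    },
    csv = utils::write.table(px, path, sep = ",", row.names = FALSE,
      col.names = FALSE),
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header columns `path,label` listing one image
#' per row. Entries keep file order; the distinct class labels are ordered
#' by first appearance. Duplicate image paths and missing fields are
#' errors.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with columns `path` and `label`, carrying the ordered
#'   label set as attribute `"labels"`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest '%s' does not exist", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("path", "label") %in% names(df))) {
    stop(sprintf("manifest '%s' must have header columns path,label", path),
      call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("manifest '%s' lists no images", path), call. = FALSE)
  }
  as_manifest(tibble::as_tibble(df[, c("path", "label")]))
}

# Validate a path/label table and attach the ordered label set.
as_manifest <- function(df) {
  if (anyNA(df$path) || anyNA(df$label) ||
      any(!nzchar(df$path)) || any(!nzchar(df$label))) {
    stop("manifest rows must have non-empty path and label fields", call. = FALSE)
  }
  if (anyDuplicated(df$path)) {
    stop(sprintf(
      "manifest contains duplicate image paths: %s",
      paste(unique(df$path[duplicated(df$path)]), collapse = ", ")
    ), call. = FALSE)
  }
  structure(df, labels = unique(df$label))
}

#' @rdname read_manifest
#' @param manifest A tibble with columns `path` and `label`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  utils::write.csv(manifest[, c("path", "label")], path, row.names = FALSE,
    quote = FALSE)
  invisible(path)
}
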