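#' Read an RGB dermoscopic image
#'
#' Reads a PNG or JPEG file into an `H x W x 3` integer array with 8-bit
#' channel values in `[0, 255]`, row-major with origin at the top-left.
#' Grayscale files are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An `H x W x 3` array of integers in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    px <- jpeg::readJPEG(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  arr <- round(px * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels with value above 127 are foreground.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' Write an RGB or grayscale raster as PNG
#'
#' @param img `H x W x 3` array or `H x W` matrix on the `[0, 255]` scale.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Run-length encode a lesion mask
#'
#' Compact JSON-friendly representation of a binary mask: per-column runs
#' of foreground pixels (1-based start row, length), as used in result
#' records.
#'
#' @param mask Logical matrix.
#' @return A list with `dim` and a data frame `runs` (col, start, length).
#' @export
mask_to_rle <- function(mask) {
  runs <- lapply(seq_len(ncol(mask)), function(j) {
    r <- rle(mask[, j])
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(col = j, start = starts[keep], length = r$lengths[keep])
  })
  list(dim = dim(mask), runs = do.call(rbind, runs))
}
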