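#' Read and write instance label masks
#'
#' An instance label mask is a 2-D non-negative integer matrix: 0 is
#' background and each value k > 0 is one nucleus identity. Masks are stored
#' losslessly as single-channel images: 8-bit grayscale PNG when the largest
#' label fits in a byte, 16-bit grayscale TIFF otherwise (up to 65535
#' labels). Pixel values are the label ids; no rescaling is applied.
#'
#' RGB-encoded masks (one color per nucleus) can be decoded by passing
#' `color_table`, a named integer vector mapping hex colors (`"#RRGGBB"`) to
#' labels; reading an RGB image without one is an error.
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @param mask Integer matrix of labels, indexed `[row, col]`.
#' @param color_table Optional named integer vector decoding RGB masks.
#' @return `read_label_mask()` returns an integer matrix;
#'   `write_label_mask()` returns `path` invisibly.
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L; m[3:4, 3:4] <- 2L
#' f <- tempfile(fileext = ".png")
#' write_label_mask(m, f)
#' identical(read_label_mask(f), m)
#' @export
read_label_mask <- function(path, color_table = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    img <- tiff::readTIFF(path, as.is = TRUE)  # raw integer sample values
    bits <- NULL
  } else {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth %||% 8
  }
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    if (is.null(color_table)) {
      abort(paste0("RGB mask image without a color-to-label table; pass ",
                   "`color_table` (named vector mapping #RRGGBB to labels)."))
    }
    chan <- if (is_tiff) {
      top <- max(img)
      img / max(top, 1)
    } else img
    hex <- grDevices::rgb(chan[, , 1], chan[, , 2], chan[, , 3])
    lab <- unname(color_table[hex])
    lab[is.na(lab)] <- 0L
    return(matrix(as.integer(lab), nrow = dim(img)[1]))
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (is_tiff) {
    matrix(as.integer(round(img)), nrow = nrow(img))
  } else {
    matrix(as.integer(round(img * (2^bits - 1))), nrow = nrow(img))
  }
}

#' @rdname read_label_mask
#' @export
write_label_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask < 0) || any(mask != round(mask))) {
    abort("`mask` must contain non-negative integers.")
  }
  top <- max(mask)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (top > 255) {
      abort(paste0("Mask has ", top, " labels; 8-bit PNG holds at most 255. ",
                   "Use a .tif path for the 16-bit container."))
    }
    png::writePNG(mask / 255, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (top > 65535) abort("Mask labels exceed the 16-bit container (65535).")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                    compression = "none")
  } else {
    abort("Unsupported mask container; use .png or .tif.")
  }
  invisible(path)
}

#' Read and write RGB patch images
#'
#' H&E patches are 8-bit RGB PNG images, held in memory as numeric arrays
#' `[row, col, 3]` with values in `[0, 1]`.
#'
#' @param path PNG path.
#' @param image Numeric array `[row, col, 3]` in `[0, 1]`.
#' @return `read_patch_image()` returns the array; `write_patch_image()`
#'   returns `path` invisibly.
#' @export
read_patch_image <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_patch_image
#' @export
write_patch_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
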