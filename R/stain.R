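#' Reinhard-style stain normalization
#'
#' Matches the per-channel mean and standard deviation of an H&E image to a
#' reference in the perceptually uniform CIE Lab color space, the classic
#' channel-statistics approach to stain normalization. Applied at test time
#' so that downstream thresholds see consistent stain intensity across
#' scanners and staining batches.
#'
#' A channel with (near) zero variance in the source is mean-shifted only,
#' so uniform inputs map to the reference mean without numerical blow-up.
#' Output is clipped back to valid sRGB.
#'
#' @param image RGB array `[row, col, 3]` in `[0, 1]`.
#' @param reference Either another RGB array, or precomputed statistics from
#'   [stain_stats()].
#' @return Normalized RGB array, same shape as `image`.
#' @examples
#' img <- array(runif(48), c(4, 4, 3))
#' normalize_stains(img, reference = img)  # identity up to rounding
#' @export
normalize_stains <- function(image, reference) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  ref <- if (is.list(reference) && !is.null(reference$mean)) {
    reference
  } else {
    stain_stats(reference)
  }
  d <- dim(image)
  rgb <- matrix(image, ncol = 3)
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  m <- colMeans(lab)
  s <- apply(lab, 2, sd)
  out <- lab
  for (ch in 1:3) {
    if (is.na(s[ch]) || s[ch] < 1e-8) {
      out[, ch] <- lab[, ch] - m[ch] + ref$mean[ch]
    } else {
      out[, ch] <- (lab[, ch] - m[ch]) / s[ch] * ref$sd[ch] + ref$mean[ch]
    }
  }
  back <- grDevices::convertColor(out, from = "Lab", to = "sRGB")
  array(pmin(pmax(back, 0), 1), d)
}

#' @rdname normalize_stains
#' @export
stain_stats <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  lab <- grDevices::convertColor(matrix(image, ncol = 3),
                                 from = "sRGB", to = "Lab")
  s <- apply(lab, 2, sd)
  s[is.na(s)] <- 0
  list(mean = colMeans(lab), sd = s)
}
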