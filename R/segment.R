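#' Marker-controlled instance separation of two-head model outputs
#'
#' Turns a nuclear-material probability map and a nuclear-center detection
#' map into an instance label mask:
#'
#' 1. foreground = `prob_map >= prob_threshold`;
#' 2. markers = connected components of `det_map >= marker_threshold`
#'    intersected with the foreground;
#' 3. marker-controlled watershed: each marker grows over the foreground
#'    along an inverse-probability landscape (geodesic nearest-marker region
#'    growing, [EBImage::propagate()]), so touching nuclei split at the
#'    ridge between their detected centers;
#' 4. foreground components holding no marker are kept as instances of their
#'    own (favoring recall; set `keep_markerless = FALSE` to drop them);
#' 5. instances smaller than `min_area` pixels are removed and labels
#'    renumbered consecutively in raster-scan order.
#'
#' @param pair A `model_output_pair` (see [derive_model_maps()]), or `NULL`
#'   when `prob_map` and `det_map` are given directly.
#' @param prob_map,det_map Matrices in `[0, 1]` with identical dimensions.
#' @param prob_threshold Foreground threshold on the probability map.
#' @param marker_threshold Threshold on the detection map.
#' @param min_area Minimum instance area in pixels (default 9 px at 40X,
#'   about a 0.75 micron-wide object).
#' @param keep_markerless Keep foreground components without any marker?
#' @return An integer instance label matrix with consecutive labels `1..K`.
#' @export
segment_instances <- function(pair = NULL, prob_map = NULL, det_map = NULL,
                              prob_threshold = 0.5, marker_threshold = 0.5,
                              min_area = 9, keep_markerless = TRUE) {
  if (!is.null(pair)) {
    prob_map <- pair$prob_map
    det_map <- pair$det_map
  }
  if (is.null(prob_map) || is.null(det_map)) {
    abort("Provide either `pair` or both `prob_map` and `det_map`.")
  }
  if (!all(dim(prob_map) == dim(det_map))) {
    abort("prob_map and det_map must share the same dimensions.")
  }
  stopifnot(prob_threshold > 0, prob_threshold < 1,
            marker_threshold > 0, marker_threshold < 1, min_area >= 1)
  fg <- prob_map >= prob_threshold
  if (!any(fg)) return(matrix(0L, nrow(prob_map), ncol(prob_map)))
  markers <- EBImage::bwlabel((det_map >= marker_threshold & fg) * 1)
  seg <- if (max(markers) > 0) {
    m <- EBImage::propagate(x = 1 - prob_map, seeds = markers, mask = fg,
                            lambda = 1e4)
    matrix(as.integer(m), nrow(prob_map))
  } else {
    matrix(0L, nrow(prob_map), ncol(prob_map))
  }
  orphan <- fg & seg == 0
  if (any(orphan)) {
    if (keep_markerless) {
      extra <- matrix(as.integer(EBImage::bwlabel(orphan * 1)), nrow(prob_map))
      seg[extra > 0] <- extra[extra > 0] + max(seg)
    }
  }
  relabel_consecutive(seg, min_area = min_area)
}

# renumber labels 1..K in raster-scan order of first occurrence (column-major,
# matching matrix storage); drops labels with < min_area pixels
relabel_consecutive <- function(mask, min_area = 1) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!any(mask > 0)) return(mask)
  counts <- tabulate(mask[mask > 0])
  keep <- which(counts >= min_area)
  first <- match(keep, mask)  # position of first pixel per kept label
  keep <- keep[order(first)]
  lut <- integer(max(mask) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  matrix(lut[mask + 1L], nrow(mask))
}

#' Convert a label mask to nucleus polygon records
#'
#' Extracts, for every instance in a label mask, its exact pixel area, its
#' size projected to 40X, and its outer boundary polygon (the ordered chain
#' of boundary pixel coordinates, 0-based, x = column / y = row).
#' Rasterizing the polygon recovers the instance up to a one-pixel boundary
#' band. Objects thinner than 3 boundary pixels get their bounding-box
#' corners as the polygon so every record carries >= 3 vertices.
#'
#' @param mask Integer instance label matrix.
#' @param scan_magnification Magnification of the pixel grid (e.g. 40, 20).
#' @return A nucleus record tibble (see [nucleus_records()]), one row per
#'   label in ascending label order.
#' @export
labels_to_records <- function(mask, scan_magnification = 40) {
  if (scan_magnification <= 0) abort("`scan_magnification` must be positive.")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  labels <- sort(unique(mask[mask > 0]))
  if (!length(labels)) {
    return(tibble(area_in_pixels = integer(), physical_size = double(),
                  polygon = list()))
  }
  areas <- tabulate(mask[mask > 0])[labels]
  # ocontour expects consecutive labels; walks the outer boundary per object,
  # 0-based (row, col) coords
  lut <- integer(max(labels) + 1L)
  lut[labels + 1L] <- seq_along(labels)
  cmask <- matrix(lut[mask + 1L], nrow(mask))
  contours <- EBImage::ocontour(cmask)
  polys <- lapply(seq_along(labels), function(i) {
    lb <- labels[i]
    ct <- contours[[i]]
    if (!is.null(ct) && nrow(ct) >= 3) {
      cbind(x = ct[, 2], y = ct[, 1])
    } else {
      idx <- which(mask == lb, arr.ind = TRUE)
      y0 <- min(idx[, 1]) - 1L; y1 <- max(idx[, 1]) - 1L
      x0 <- min(idx[, 2]) - 1L; x1 <- max(idx[, 2]) - 1L
      cbind(x = c(x0, x0, x1, x1), y = c(y0, y1, y1, y0))
    }
  })
  nucleus_records(area_in_pixels = areas, polygon = polys,
                  scan_magnification = scan_magnification)
}

#' Plan the tile grid for a whole slide
#'
#' Whole-slide segmentation results are produced and stored in
#' `tile_size` x `tile_size` pixel tiles laid out row-major from the slide
#' origin, with edge tiles truncated to the slide bounds. Truncated tiles
#' whose width **or** height falls strictly below `min_edge` pixels are not
#' segmented (this happens at slide edges) and are excluded from the grid;
#' the exclusion is strict, so a 2000-pixel edge is kept. Nuclei split
#' across tile borders stay split — a known by-design error of tiled
#' processing.
#'
#' @param slide_width,slide_height Slide dimensions in pixels.
#' @param tile_size Tile edge length (default 4000).
#' @param min_edge Minimum retained edge length (default 2000, strict).
#' @return A tibble of class `"tile_grid"` with columns `x_origin`,
#'   `y_origin`, `width`, `height`, in row-major order, and attributes
#'   `slide_width` / `slide_height`.
#' @examples
#' plan_tiles(9000, 5000)   # 2 tiles: the 1000-px margins are skipped
#' plan_tiles(10000, 6000)  # 6 tiles: 2000-px edges are kept
#' @export
plan_tiles <- function(slide_width, slide_height, tile_size = 4000,
                       min_edge = 2000) {
  stopifnot(slide_width > 0, slide_height > 0, tile_size > 0, min_edge >= 0)
  xs <- seq(0L, slide_width - 1L, by = tile_size)
  ys <- seq(0L, slide_height - 1L, by = tile_size)
  grid <- tidyr::expand_grid(y_origin = as.integer(ys), x_origin = as.integer(xs))
  grid <- mutate(grid,
                 width = pmin(tile_size, slide_width - .data$x_origin),
                 height = pmin(tile_size, slide_height - .data$y_origin))
  grid <- filter(grid, .data$width >= min_edge, .data$height >= min_edge)
  out <- select(grid, "x_origin", "y_origin", "width", "height")
  attr(out, "slide_width") <- slide_width
  attr(out, "slide_height") <- slide_height
  class(out) <- c("tile_grid", class(out))
  out
}
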