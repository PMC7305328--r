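#' Nucleus polygon records
#'
#' A nucleus record table is the in-memory form of the polygon contour CSV
#' that accompanies each segmented tile: one row per nucleus with its pixel
#' area at scan resolution, its size projected to 40X, and its boundary
#' polygon. `nucleus_records()` builds and validates such a table.
#'
#' Conventions used throughout the package: label masks are integer matrices
#' indexed `[row, col]`; polygon vertices are 0-based pixel coordinates with
#' `x` = column and `y` = row, so vertex `(x, y)` addresses matrix cell
#' `[y + 1, x + 1]`. Polygons are closed implicitly (last vertex connects
#' back to the first) and must have at least 3 vertices. The physical size is
#' the pixel count projected to the 40X reference magnification:
#' `physical_size = area_in_pixels * (40 / scan_magnification)^2`.
#'
#' @param area_in_pixels Integer vector, foreground pixel count per nucleus
#'   (each >= 1).
#' @param polygon List of numeric matrices, one per nucleus, each with two
#'   columns `x`, `y` and >= 3 rows.
#' @param scan_magnification Magnification the pixel grid was scanned at
#'   (40 for 0.25 micron pixels). Used to project areas to 40X.
#'
#' @return A tibble with columns `area_in_pixels` (integer),
#'   `physical_size` (double) and `polygon` (list of matrices).
#' @examples
#' sq <- cbind(x = c(0, 0, 2, 2), y = c(0, 2, 2, 0))
#' nucleus_records(area_in_pixels = 9, polygon = list(sq))
#' @export
nucleus_records <- function(area_in_pixels, polygon, scan_magnification = 40) {
  area_in_pixels <- as.integer(area_in_pixels)
  if (!is.list(polygon)) polygon <- list(polygon)
  if (length(area_in_pixels) != length(polygon)) {
    abort("`area_in_pixels` and `polygon` must have the same length.")
  }
  if (scan_magnification <= 0) {
    abort("`scan_magnification` must be positive.")
  }
  polygon <- lapply(polygon, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    p
  })
  records <- tibble(
    area_in_pixels = area_in_pixels,
    physical_size  = area_in_pixels * (40 / scan_magnification)^2,
    polygon        = polygon
  )
  validate_nucleus_records(records)
  records
}

validate_nucleus_records <- function(records) {
  stopifnot(all(c("area_in_pixels", "physical_size", "polygon") %in% names(records)))
  bad_area <- which(records$area_in_pixels < 1)
  if (length(bad_area)) {
    abort(paste0("area_in_pixels must be >= 1; violated at row(s) ",
                 paste(head(bad_area, 5), collapse = ", "), "."))
  }
  nv <- vapply(records$polygon, nrow, integer(1))
  bad_poly <- which(nv < 3)
  if (length(bad_poly)) {
    abort(paste0("polygon must have >= 3 vertices; violated at row(s) ",
                 paste(head(bad_poly, 5), collapse = ", "), "."))
  }
  invisible(records)
}

# "[x0:y0:x1:y1:...]"; integral coordinates print without decimals,
# the rest with 2 decimal places (keeps files compact and round-trip stable)
polygon_to_string <- function(p) {
  v <- as.numeric(t(p[, c("x", "y"), drop = FALSE]))
  s <- ifelse(v == round(v), format(round(v), scientific = FALSE, trim = TRUE),
              formatC(v, format = "f", digits = 2))
  paste0("[", paste(s, collapse = ":"), "]")
}

string_to_polygon <- function(s, row = NA) {
  body <- sub("^\\[", "", sub("\\]$", "", trimws(s)))
  tok <- strsplit(body, ":", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(tok))
  if (length(v) %% 2 != 0 || anyNA(v)) {
    abort(paste0("Malformed polygon string at row ", row,
                 ": expected an even count of numeric tokens in [x0:y0:...]."))
  }
  m <- matrix(v, ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Write and read polygon contour CSV files
#'
#' The polygon CSV holds one segmented nucleus per row in three columns:
#' `AreaInPixels`, `PhysicalSize` and `Polygon`, the last serialized as a
#' bracketed colon-separated vertex string `[x0:y0:x1:y1:...]`. Row order is
#' preserved. When a tile of a larger slide is described, the tile origin is
#' carried in the file name (`<x>_<y>_polygon.csv`), not in the coordinates,
#' which stay in the tile's own pixel grid.
#'
#' @param records A nucleus record tibble, see [nucleus_records()].
#' @param path Destination (writer) or source (reader) CSV path.
#' @return `write_polygon_csv()` returns `path` invisibly;
#'   `read_polygon_csv()` returns a nucleus record tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sq <- cbind(x = c(0, 0, 2, 2), y = c(0, 2, 2, 0))
#' write_polygon_csv(nucleus_records(9, list(sq)), f)
#' read_polygon_csv(f)
#' @export
write_polygon_csv <- function(records, path) {
  validate_nucleus_records(records)
  out <- data.frame(
    AreaInPixels = records$area_in_pixels,
    PhysicalSize = ifelse(records$physical_size == round(records$physical_size),
                          format(round(records$physical_size), scientific = FALSE,
                                 trim = TRUE),
                          formatC(records$physical_size, format = "f", digits = 4)),
    Polygon = vapply(records$polygon, polygon_to_string, character(1)),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_polygon_csv
#' @export
read_polygon_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  expected <- c("AreaInPixels", "PhysicalSize", "Polygon")
  if (!identical(names(raw), expected)) {
    abort(paste0("Unexpected polygon CSV header: ",
                 paste(names(raw), collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(area_in_pixels = integer(), physical_size = double(),
                  polygon = list()))
  }
  area <- suppressWarnings(as.numeric(raw$AreaInPixels))
  if (anyNA(area) || any(area != round(area))) {
    abort(paste0("Non-integer AreaInPixels at row(s) ",
                 paste(head(which(is.na(area) | area != round(area)), 5),
                       collapse = ", "), "."))
  }
  polys <- lapply(seq_len(nrow(raw)),
                  function(i) string_to_polygon(raw$Polygon[i], row = i))
  records <- tibble(
    area_in_pixels = as.integer(area),
    physical_size  = as.numeric(raw$PhysicalSize),
    polygon        = polys
  )
  validate_nucleus_records(records)
  records
}
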