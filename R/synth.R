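#' Synthetic patch generator configuration
#'
#' `synth_config()` describes how synthetic H&E-like patches are generated:
#' random star-shaped polygons stand in for nuclei (nuclear masks as random
#' polygons), rendered with parametric hematoxylin/eosin colors, Gaussian
#' blur and additive noise. Defaults emulate a 256 x 256 pixel patch at 40X
#' (0.25 micron pixels) holding a few tens of convex-ish nuclei.
#'
#' @param patch_size Patch edge length in pixels.
#' @param nucleus_count_range Integer interval `c(lo, hi)` for the nucleus
#'   count per patch.
#' @param radius_range Base polygon radius interval in pixels; must fit
#'   inside the patch.
#' @param vertex_count_range Integer interval for polygon vertex counts
#'   (each >= 5).
#' @param irregularity Radial jitter fraction in `[0, 1)` — the synthetic
#'   analogue of nuclear pleomorphism. Vertex radii are drawn as
#'   `base_radius * (1 + irregularity * u)`, `u ~ U(-1, 1)`.
#' @param min_gap Minimum pixel gap enforced between distinct nuclei.
#' @param nucleus_color,background_color RGB triples in `[0, 1]` emulating
#'   hematoxylin-stained chromatin and eosin-stained background.
#' @param blur_sigma Gaussian blur applied to the rendered image, pixels.
#' @param noise_std Standard deviation of additive rendering noise.
#' @param seed Integer seed; every artifact of the generator is a pure
#'   function of its config seed.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(patch_size = 256,
                         nucleus_count_range = c(20, 40),
                         radius_range = c(4, 10),
                         vertex_count_range = c(8, 14),
                         irregularity = 0.25,
                         min_gap = 3,
                         nucleus_color = c(0.35, 0.22, 0.50),
                         background_color = c(0.91, 0.79, 0.84),
                         blur_sigma = 1,
                         noise_std = 0.03,
                         seed = 1L) {
  cfg <- list(patch_size = as.integer(patch_size),
              nucleus_count_range = as.integer(round(nucleus_count_range)),
              radius_range = as.numeric(radius_range),
              vertex_count_range = as.integer(round(vertex_count_range)),
              irregularity = irregularity, min_gap = as.integer(min_gap),
              nucleus_color = nucleus_color,
              background_color = background_color,
              blur_sigma = blur_sigma, noise_std = noise_std,
              seed = as.integer(seed))
  stopifnot(cfg$patch_size >= 8,
            length(cfg$nucleus_count_range) == 2,
            diff(cfg$nucleus_count_range) >= 0,
            cfg$nucleus_count_range[1] >= 0,
            length(cfg$radius_range) == 2,
            cfg$radius_range[1] > 0,
            diff(cfg$radius_range) >= 0,
            cfg$vertex_count_range[1] >= 5,
            diff(cfg$vertex_count_range) >= 0,
            cfg$irregularity >= 0, cfg$irregularity < 1,
            cfg$blur_sigma >= 0, cfg$noise_std >= 0)
  if (2 * cfg$radius_range[2] * (1 + cfg$irregularity) >= cfg$patch_size) {
    abort("radius_range does not fit inside the patch.")
  }
  structure(cfg, class = "synth_config")
}

#' Model-output corruption configuration
#'
#' Controls how the ideal model-output maps derived from a ground-truth mask
#' are degraded, so that detection/segmentation error rates can be injected
#' at known levels and recovered by the evaluation suite.
#'
#' @param fn_rate Probability in `[0, 1]` that a true nucleus is erased from
#'   both maps (a false negative).
#' @param fp_count Number of spurious blobs added to both maps in background
#'   (false positives).
#' @param boundary_shift Signed integer pixels: dilate (+) or erode (-) the
#'   foreground before map synthesis.
#' @param map_noise_std Additive Gaussian noise on map values; maps are
#'   clipped back to `[0, 1]`.
#' @param seed Integer seed for the corruption draws.
#' @return A validated list of class `"corruption_config"`.
#' @export
corruption_config <- function(fn_rate = 0, fp_count = 0L, boundary_shift = 0L,
                              map_noise_std = 0, seed = 1L) {
  cfg <- list(fn_rate = fn_rate, fp_count = as.integer(fp_count),
              boundary_shift = as.integer(boundary_shift),
              map_noise_std = map_noise_std, seed = as.integer(seed))
  stopifnot(cfg$fn_rate >= 0, cfg$fn_rate <= 1, cfg$fp_count >= 0,
            cfg$map_noise_std >= 0)
  structure(cfg, class = "corruption_config")
}

# star polygon around (0,0): angles jittered on a regular grid, radii
# jittered by +/- irregularity
star_polygon <- function(base_radius, n_vertices, irregularity) {
  step <- 2 * pi / n_vertices
  ang <- sort((seq_len(n_vertices) - 1) * step +
                runif(n_vertices, -0.45, 0.45) * step)
  rad <- base_radius * (1 + irregularity * runif(n_vertices, -1, 1))
  cbind(x = rad * cos(ang), y = rad * sin(ang))
}

# even-odd rasterization of a polygon onto integer pixel centers
rasterize_polygon <- function(poly, patch_size) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- max(0L, floor(xr[1])):min(patch_size - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(patch_size - 1L, ceiling(yr[2]))
  if (!length(xs) || !length(ys)) return(NULL)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (!any(inside)) return(NULL)
  cbind(x = px[inside], y = py[inside])
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Generate a random instance label mask
#'
#' Draws a nucleus count from `nucleus_count_range`, then places that many
#' star-shaped polygons by rejection sampling so that nuclei are pairwise
#' disjoint with at least `min_gap` pixels between them, and rasterizes each
#' to >= 1 pixel. Labels are consecutive `1..K`. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param max_attempts Placement attempt budget per requested nucleus.
#' @return An integer label matrix of size `patch_size x patch_size` with
#'   attribute `"nuclei"`: a tibble of per-nucleus label, seed center and
#'   base radius.
#' @export
generate_instance_mask <- function(config, max_attempts = 200) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_instance_mask_impl(config, max_attempts))
}

generate_instance_mask_impl <- function(config, max_attempts = 200) {
  ps <- config$patch_size
  k_target <- if (diff(config$nucleus_count_range) == 0) {
    config$nucleus_count_range[1]
  } else {
    sample(config$nucleus_count_range[1]:config$nucleus_count_range[2], 1)
  }
  mask <- matrix(0L, ps, ps)
  blocked <- matrix(FALSE, ps, ps)  # occupied + gap halo
  info <- vector("list", k_target)
  placed <- 0L
  if (k_target > 0) {
    for (k in seq_len(k_target)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        r <- runif(1, config$radius_range[1], config$radius_range[2])
        nv <- if (diff(config$vertex_count_range) == 0) {
          config$vertex_count_range[1]
        } else {
          sample(config$vertex_count_range[1]:config$vertex_count_range[2], 1)
        }
        margin <- r * (1 + config$irregularity) + 1
        cx <- runif(1, margin, ps - 1 - margin)
        cy <- runif(1, margin, ps - 1 - margin)
        poly <- star_polygon(r, nv, config$irregularity)
        poly <- cbind(x = poly[, "x"] + cx, y = poly[, "y"] + cy)
        pix <- rasterize_polygon(poly, ps)
        if (is.null(pix)) next
        idx <- cbind(pix[, "y"] + 1L, pix[, "x"] + 1L)
        if (any(blocked[idx])) next
        placed <- placed + 1L
        mask[idx] <- placed
        # halo: block a square neighborhood of min_gap around each pixel
        g <- config$min_gap
        for (dy in -g:g) for (dx in -g:g) {
          yy <- pmin(pmax(idx[, 1] + dy, 1L), ps)
          xx <- pmin(pmax(idx[, 2] + dx, 1L), ps)
          blocked[cbind(yy, xx)] <- TRUE
        }
        info[[placed]] <- tibble(label = placed, center_x = cx, center_y = cy,
                                 base_radius = r,
                                 polygon_area = shoelace_area(poly),
                                 area = nrow(pix))
        ok <- TRUE
        break
      }
      if (!ok) {
        if (placed < config$nucleus_count_range[1]) {
          abort(paste0("Could not place the requested nuclei: achieved ",
                       placed, " of at least ", config$nucleus_count_range[1],
                       " within the attempt budget."))
        }
        break
      }
    }
  }
  attr(mask, "nuclei") <- if (placed > 0) {
    dplyr::bind_rows(info[seq_len(placed)])
  } else {
    tibble(label = integer(), center_x = double(), center_y = double(),
           base_radius = double(), polygon_area = double(), area = integer())
  }
  mask
}

#' Render a synthetic H&E-like patch from a label mask
#'
#' Nucleus pixels are drawn near `nucleus_color` and background near
#' `background_color` (hematoxylin darker than eosin), then the image is
#' Gaussian-blurred and perturbed with additive noise. Deterministic given
#' `config$seed`. The paper-grade texture synthesis / adversarial refinement
#' used to train CNNs is deliberately not emulated; this rendering exercises
#' stain statistics and the post-processing pipeline, not CNN realism.
#'
#' @param mask Integer label matrix.
#' @param config A [synth_config()] whose `patch_size` matches `mask`.
#' @return RGB array `[row, col, 3]` in `[0, 1]`.
#' @export
render_patch <- function(mask, config) {
  stopifnot(inherits(config, "synth_config"))
  if (!all(dim(mask) == config$patch_size)) {
    abort("`mask` dimensions do not match `config$patch_size`.")
  }
  withr::with_seed(config$seed + 1L, {
    fg <- mask > 0
    img <- array(0, c(dim(mask), 3))
    for (ch in 1:3) {
      plane <- ifelse(fg, config$nucleus_color[ch], config$background_color[ch])
      if (config$blur_sigma > 0) {
        plane <- as.matrix(EBImage::gblur(plane, sigma = config$blur_sigma))
      }
      if (config$noise_std > 0) {
        plane <- plane + rnorm(length(plane), 0, config$noise_std)
      }
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    img
  })
}

# place a gaussian bump (peak 1, truncated at 3 sigma) on `map` centered at
# pixel (cy, cx) [1-based]; returns the updated map
add_bump <- function(map, cy, cx, sigma) {
  ps <- nrow(map)
  ext <- ceiling(3 * sigma)
  ys <- max(1L, cy - ext):min(ps, cy + ext)
  xs <- max(1L, cx - ext):min(ncol(map), cx + ext)
  dy <- (ys - cy); dx <- (xs - cx)
  d2 <- outer(dy^2, dx^2, "+")
  bump <- exp(-d2 / (2 * sigma^2))
  bump[d2 > (3 * sigma)^2] <- 0
  map[ys, xs] <- pmax(map[ys, xs], bump)
  map
}

#' Derive two-head model-output maps from a ground-truth mask
#'
#' Builds the pair of maps a segmentation network's two output heads would
#' produce for a perfectly segmented patch, then applies controlled
#' corruption. The nuclear-material probability map is
#' `0.5 * indicator + 0.5 * blur(indicator)` of the (possibly
#' boundary-shifted) foreground, so that thresholding at 0.5 recovers the
#' foreground exactly when uncorrupted. The detection map holds a Gaussian
#' bump of peak 1.0 (sigma = equivalent radius / 2, truncated at 3 sigma) at
#' each surviving nucleus center, plus `fp_count` spurious blobs placed in
#' background on both maps.
#'
#' @param mask Integer label matrix (ground truth).
#' @param corruption A [corruption_config()].
#' @param smooth_sigma Blur applied to the probability map, pixels.
#' @return A list of class `"model_output_pair"`: `prob_map`, `det_map`
#'   (matrices in `[0, 1]`) and `provenance`, a tibble with one row per true
#'   nucleus (`label`, `center_x`, `center_y`, `area`, `erased`) followed by
#'   rows for injected false positives (`label = NA`).
#' @export
derive_model_maps <- function(mask, corruption = corruption_config(),
                              smooth_sigma = 1) {
  stopifnot(inherits(corruption, "corruption_config"))
  withr::with_seed(corruption$seed,
                   derive_model_maps_impl(mask, corruption, smooth_sigma))
}

derive_model_maps_impl <- function(mask, corruption, smooth_sigma) {
  labels <- sort(unique(mask[mask > 0]))
  k <- length(labels)
  erased <- if (k > 0) runif(k) < corruption$fn_rate else logical(0)
  kept <- matrix(0L, nrow(mask), ncol(mask))
  prov <- vector("list", k)
  det <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(k)) {
    sel <- mask == labels[i]
    idx <- which(sel, arr.ind = TRUE)
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    # anchor the bump on the object pixel nearest the centroid (stays inside)
    near <- which.min((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
    prov[[i]] <- tibble(label = labels[i], center_x = cx - 1, center_y = cy - 1,
                        area = nrow(idx), erased = erased[i])
    if (erased[i]) next
    kept[sel] <- labels[i]
    sigma <- sqrt(nrow(idx) / pi) / 2
    det <- add_bump(det, idx[near, 1], idx[near, 2], max(sigma, 0.8))
  }
  fg <- kept > 0
  if (corruption$boundary_shift != 0) {
    brush <- EBImage::makeBrush(2 * abs(corruption$boundary_shift) + 1, "disc")
    fg <- if (corruption$boundary_shift > 0) {
      as.matrix(EBImage::dilate(fg * 1, brush)) > 0
    } else {
      as.matrix(EBImage::erode(fg * 1, brush)) > 0
    }
  }
  # false positives: disk in the probability map + bump in the detection map,
  # placed in background clear of true foreground
  fp_rows <- list()
  if (corruption$fp_count > 0) {
    clear <- as.matrix(EBImage::dilate((mask > 0) * 1,
                                       EBImage::makeBrush(9, "disc"))) > 0
    free <- which(!clear, arr.ind = TRUE)
    n_fp <- min(corruption$fp_count, nrow(free))
    if (n_fp > 0) {
      pick <- free[sample(nrow(free), n_fp), , drop = FALSE]
      for (j in seq_len(n_fp)) {
        r <- stats::median(c(3, sqrt(mean(table(mask[mask > 0])) / pi), 6))
        yy <- pick[j, 1]; xx <- pick[j, 2]
        dj <- outer((seq_len(nrow(fg)) - yy)^2, (seq_len(ncol(fg)) - xx)^2, "+")
        fg <- fg | (dj <= r^2)
        det <- add_bump(det, yy, xx, max(r / 2, 0.8))
        fp_rows[[j]] <- tibble(label = NA_integer_, center_x = xx - 1,
                               center_y = yy - 1, area = sum(dj <= r^2),
                               erased = FALSE)
      }
    }
  }
  ind <- fg * 1
  prob <- 0.5 * ind +
    0.5 * as.matrix(EBImage::gblur(ind, sigma = max(smooth_sigma, 0.3)))
  if (corruption$map_noise_std > 0) {
    prob <- prob + rnorm(length(prob), 0, corruption$map_noise_std)
    det <- det + rnorm(length(det), 0, corruption$map_noise_std)
  }
  provenance <- dplyr::bind_rows(c(prov[seq_len(k)], fp_rows))
  if (k == 0 && !length(fp_rows)) {
    provenance <- tibble(label = integer(), center_x = double(),
                         center_y = double(), area = integer(),
                         erased = logical())
  }
  structure(list(prob_map = pmin(pmax(prob, 0), 1),
                 det_map = pmin(pmax(det, 0), 1),
                 provenance = provenance),
            class = "model_output_pair")
}

#' Generate a complete synthetic patch
#'
#' Convenience wrapper producing a ground-truth mask, its rendered H&E-like
#' image, and (optionally corrupted) two-head model-output maps in one call.
#'
#' @inheritParams generate_instance_mask
#' @param corruption A [corruption_config()].
#' @return A list of class `"synth_patch"` with `image`, `truth_mask`,
#'   `prob_map`, `det_map` and `provenance`.
#' @export
generate_patch <- function(config = synth_config(),
                           corruption = corruption_config()) {
  mask <- generate_instance_mask(config)
  img <- render_patch(mask, config)
  maps <- derive_model_maps(mask, corruption)
  structure(list(image = img, truth_mask = mask, prob_map = maps$prob_map,
                 det_map = maps$det_map, provenance = maps$provenance),
            class = "synth_patch")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_patches` synthetic patches (image, ground-truth mask, both
#' model-output maps) plus a manifest CSV recording file names, per-patch
#' seeds and truth counts. Per-patch seeds are derived deterministically from
#' the config seeds, so the whole dataset is reproducible from the manifest.
#'
#' @param n_patches Number of patches.
#' @param config A [synth_config()]; its `seed` is the master seed.
#' @param corruption A [corruption_config()].
#' @param dir Destination directory.
#' @param overwrite Overwrite an existing manifest? Default `FALSE`.
#' @return The manifest path, invisibly.
#' @export
generate_dataset <- function(n_patches, config = synth_config(),
                             corruption = corruption_config(), dir,
                             overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    abort(paste0("Manifest already exists at ", manifest_path,
                 "; pass overwrite = TRUE to replace the dataset."))
  }
  rows <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    cfg_i <- config; cfg_i$seed <- config$seed + i
    cor_i <- corruption; cor_i$seed <- corruption$seed + i
    sp <- generate_patch(cfg_i, cor_i)
    stem <- sprintf("patch_%04d", i)
    write_patch_image(sp$image, file.path(dir, paste0(stem, "_image.png")))
    write_label_mask(sp$truth_mask, file.path(dir, paste0(stem, "_mask.tif")))
    png::writePNG(sp$prob_map, file.path(dir, paste0(stem, "_prob.png")))
    png::writePNG(sp$det_map, file.path(dir, paste0(stem, "_det.png")))
    rows[[i]] <- tibble(
      patch = stem, image = paste0(stem, "_image.png"),
      mask = paste0(stem, "_mask.tif"), prob_map = paste0(stem, "_prob.png"),
      det_map = paste0(stem, "_det.png"),
      synth_seed = cfg_i$seed, corruption_seed = cor_i$seed,
      truth_count = max(sp$truth_mask),
      surviving_count = sum(!sp$provenance$erased[!is.na(sp$provenance$label)])
    )
  }
  manifest <- if (n_patches > 0) dplyr::bind_rows(rows) else {
    tibble(patch = character(), image = character(), mask = character(),
           prob_map = character(), det_map = character(),
           synth_seed = integer(), corruption_seed = integer(),
           truth_count = integer(), surviving_count = integer())
  }
  write.csv(as.data.frame(manifest), manifest_path, row.names = FALSE,
            quote = FALSE)
  invisible(manifest_path)
}
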