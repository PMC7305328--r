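#' Quality-control thresholds
#'
#' Bundles the tunable constants of the two-level QC process:
#'
#' * `pr_min` — a sampled region is adequate when both object precision and
#'   recall reach this value (default 0.75, inclusive);
#' * `slide_adequate_fraction` — a slide is acceptable when at least this
#'   fraction of it is adequate (default 0.80, inclusive);
#' * `patches_per_wsi` — regions sampled per slide (default 15, each
#'   256 x 256 pixels at 40X);
#' * `tail_fraction` — fraction of slides flagged per tail per statistic in
#'   outlier selection (default 0.02, doubled under escalation);
#' * `group_boundaries` — upper-inclusive percentage cut points of the
#'   bad-region fraction separating Good / Adequate / Problematic /
#'   Unacceptable. The defaults are the exact 1/15, 2/15, 3/15 breakpoints
#'   (printed rounded as 6.67 / 13.3 / 20.0) so that k of 15 bad regions
#'   maps to the k-th group.
#'
#' @param pr_min,slide_adequate_fraction,patches_per_wsi,tail_fraction,group_boundaries
#'   See above.
#' @return A validated list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(pr_min = 0.75, slide_adequate_fraction = 0.80,
                          patches_per_wsi = 15L, tail_fraction = 0.02,
                          group_boundaries = c(100 / 15, 200 / 15, 20)) {
  th <- list(pr_min = pr_min,
             slide_adequate_fraction = slide_adequate_fraction,
             patches_per_wsi = as.integer(patches_per_wsi),
             tail_fraction = tail_fraction,
             group_boundaries = group_boundaries)
  stopifnot(th$pr_min > 0, th$pr_min < 1,
            th$slide_adequate_fraction > 0, th$slide_adequate_fraction <= 1,
            th$patches_per_wsi >= 1,
            th$tail_fraction > 0, th$tail_fraction < 0.5,
            length(th$group_boundaries) == 3,
            all(diff(th$group_boundaries) > 0),
            th$group_boundaries[1] > 0, th$group_boundaries[3] < 100)
  structure(th, class = "qc_thresholds")
}

.quality_groups <- c("Best", "Good", "Adequate", "Problematic", "Unacceptable")

#' Sample random region locations on a slide
#'
#' Uniformly samples `n` patch origins (0-based x, y) such that each
#' `patch_size` square lies fully inside the slide. Origins are distinct
#' whenever the slide offers at least `n` placements. Deterministic given
#' `seed`.
#'
#' @param slide_width,slide_height Slide dimensions in pixels.
#' @param n Number of regions, default 15.
#' @param patch_size Region edge length, default 256 (at 40X).
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_patch_locations <- function(slide_width, slide_height, n = 15,
                                   patch_size = 256, seed = 1L) {
  if (slide_width < patch_size || slide_height < patch_size) {
    abort("Slide is smaller than the patch size.")
  }
  wx <- slide_width - patch_size + 1
  wy <- slide_height - patch_size + 1
  withr::with_seed(as.integer(seed), {
    if (as.double(wx) * wy >= n) {
      pos <- integer(0)
      while (length(pos) < n) {
        cand <- floor(runif(n - length(pos), 0, as.double(wx) * wy))
        pos <- unique(c(pos, cand))
      }
      pos <- pos[seq_len(n)]
    } else {
      pos <- floor(runif(n, 0, as.double(wx) * wy))
    }
    tibble(x = as.integer(pos %% wx), y = as.integer(pos %/% wx))
  })
}

#' Is a sampled region's segmentation adequate?
#'
#' A region counts as adequately segmented when both object precision and
#' recall are at least `pr_min` (boundary inclusive). Vectorized.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param thresholds A [qc_thresholds()].
#' @return Logical vector.
#' @export
patch_adequate <- function(precision, recall, thresholds = qc_thresholds()) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  precision >= thresholds$pr_min & recall >= thresholds$pr_min
}

#' Categorize a slide into a quality group
#'
#' From the number of badly segmented regions among those sampled, assigns
#' one of Best / Good / Adequate / Problematic / Unacceptable: Best at
#' exactly 0% bad, then the upper-inclusive `group_boundaries` percentage
#' intervals, Unacceptable beyond the last cut point. A failed visual
#' slide-level assessment forces Unacceptable regardless of the region
#' fraction. Vectorized over slides.
#'
#' @param num_bad Number of bad (inadequate) sampled regions.
#' @param num_sampled Number of judged sampled regions (>= 1).
#' @param visual_fail Logical, slide failed visual WSI-level QC.
#' @param thresholds A [qc_thresholds()].
#' @return Factor with levels Best, Good, Adequate, Problematic,
#'   Unacceptable.
#' @export
classify_wsi <- function(num_bad, num_sampled, visual_fail = FALSE,
                         thresholds = qc_thresholds()) {
  n <- max(length(num_bad), length(num_sampled), length(visual_fail))
  num_bad <- rep_len(num_bad, n)
  num_sampled <- rep_len(num_sampled, n)
  visual_fail <- rep_len(visual_fail, n)
  if (any(num_sampled < 1)) abort("num_sampled must be >= 1.")
  if (any(num_bad < 0 | num_bad > num_sampled)) {
    abort("num_bad must lie in [0, num_sampled].")
  }
  pct <- 100 * num_bad / num_sampled
  b <- thresholds$group_boundaries
  eps <- 1e-9  # absorb floating error at the k/n breakpoints
  group <- dplyr::case_when(
    visual_fail ~ "Unacceptable",
    pct <= 0 ~ "Best",
    pct <= b[1] + eps ~ "Good",
    pct <= b[2] + eps ~ "Adequate",
    pct <= b[3] + eps ~ "Problematic",
    TRUE ~ "Unacceptable"
  )
  factor(group, levels = .quality_groups)
}

#' Is a slide's segmentation acceptable overall?
#'
#' A slide is acceptable if and only if at least
#' `slide_adequate_fraction` of it (default 80%, inclusive) is adequately
#' segmented — i.e. has both precision and recall at or above `pr_min`.
#'
#' @param adequate_fraction Fraction of the slide judged adequate, `[0, 1]`.
#' @param thresholds A [qc_thresholds()].
#' @return Logical vector.
#' @export
slide_acceptable <- function(adequate_fraction, thresholds = qc_thresholds()) {
  stopifnot(all(adequate_fraction >= 0 & adequate_fraction <= 1))
  adequate_fraction >= thresholds$slide_adequate_fraction
}

#' Per-slide nucleus summary statistics
#'
#' Count, arithmetic mean and population standard deviation of the
#' per-nucleus pixel areas of a slide — the three statistics screened for
#' outliers during WSI-level QC. An empty record set yields `(0, 0, 0)`.
#'
#' @param records A nucleus record tibble (see [nucleus_records()]), or a
#'   numeric vector of areas.
#' @return A one-row tibble: `num_nuclei`, `size_mean`, `size_std`.
#' @export
compute_wsi_statistics <- function(records) {
  areas <- if (is.data.frame(records)) records$area_in_pixels else records
  n <- length(areas)
  if (n == 0) return(tibble(num_nuclei = 0L, size_mean = 0, size_std = 0))
  m <- mean(areas)
  tibble(num_nuclei = n, size_mean = m,
         size_std = sqrt(sum((areas - m)^2) / n))
}

#' Select statistical outlier slides for visual assessment
#'
#' Within each cancer type and for each of the three per-slide statistics
#' (nucleus count, mean nuclear size, nuclear-size standard deviation —
#' the last reflecting apparent pleomorphism), flags the
#' `ceiling(tail_fraction * n)` most extreme slides in **each** tail by
#' rank; ties are broken by `wsi_id` lexicographic order so selection is
#' exact and deterministic. A slide can carry several reasons. Escalation
#' (`escalate = TRUE`) doubles the tail fraction — "another 2%, in total
#' 4%" — for cancer types whose first visual round looked problematic.
#'
#' @param stats A tibble with columns `wsi_id`, `cancer_type`,
#'   `num_nuclei`, `size_mean`, `size_std`.
#' @param tail_fraction Tail fraction per side, default 0.02.
#' @param escalate Double the tail fraction?
#' @return A tibble `wsi_id`, `cancer_type`, `reason` (one row per flag)
#'   with reasons among count_low/high, size_low/high, sizevar_low/high.
#' @export
select_outlier_wsis <- function(stats, tail_fraction = 0.02, escalate = FALSE) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("`tail_fraction` must lie in (0, 0.5).")
  }
  need <- c("wsi_id", "cancer_type", "num_nuclei", "size_mean", "size_std")
  if (!all(need %in% names(stats))) {
    abort(paste0("`stats` must have columns: ", paste(need, collapse = ", ")))
  }
  f <- tail_fraction * (1 + escalate)
  stat_cols <- c(count = "num_nuclei", size = "size_mean",
                 sizevar = "size_std")
  out <- list()
  for (ct in unique(stats$cancer_type)) {
    grp <- stats[stats$cancer_type == ct, ]
    m <- ceiling(f * nrow(grp))
    for (s in names(stat_cols)) {
      v <- grp[[stat_cols[[s]]]]
      lo <- order(v, grp$wsi_id)[seq_len(m)]
      hi <- order(-v, grp$wsi_id)[seq_len(m)]
      out[[length(out) + 1L]] <- tibble(
        wsi_id = grp$wsi_id[lo], cancer_type = ct,
        reason = paste0(s, "_low"))
      out[[length(out) + 1L]] <- tibble(
        wsi_id = grp$wsi_id[hi], cancer_type = ct,
        reason = paste0(s, "_high"))
    }
  }
  arrange(dplyr::bind_rows(out), .data$cancer_type, .data$wsi_id,
          .data$reason)
}

#' Materialize QC summaries and the released-data CSV tables
#'
#' Takes per-slide QC bookkeeping (sampled-region tallies, visual verdicts,
#' nucleus statistics), assigns quality groups, and writes: a per-cancer-type
#' summary (total and failed slide counts), a per-group slide count table,
#' and the three released-data CSVs (WSI list, visual QC, region checking)
#' via [write_qc_tables()]. Unjudged sampled regions are excluded from the
#' bad-fraction denominator and reported separately.
#'
#' @param wsi_qc A tibble with columns `wsi_id`, `cancer_type`, `num_bad`,
#'   `num_sampled`, and optionally `num_unjudged`, `visual_fail`,
#'   `num_nuclei`, `size_mean`, `size_std`, `note`, `comment`.
#' @param dir Destination directory.
#' @param thresholds A [qc_thresholds()].
#' @return Invisibly, a list with `records` (per-slide tibble including
#'   `quality_group` and `qc_result`), `by_cancer_type`, `by_group`, and
#'   `paths` (written files).
#' @export
qc_report <- function(wsi_qc, dir = NULL, thresholds = qc_thresholds()) {
  need <- c("wsi_id", "cancer_type", "num_bad", "num_sampled")
  if (!all(need %in% names(wsi_qc))) {
    abort(paste0("`wsi_qc` must have columns: ", paste(need, collapse = ", ")))
  }
  rec <- as_tibble(wsi_qc)
  n <- nrow(rec)
  defaults <- list(visual_fail = FALSE, num_unjudged = 0L, num_nuclei = 0L,
                   size_mean = 0, size_std = 0, note = "", comment = "")
  for (nm in names(defaults)) {
    if (!nm %in% names(rec)) rec[[nm]] <- rep(defaults[[nm]], n)
  }
  rec$quality_group <- classify_wsi(rec$num_bad, rec$num_sampled,
                                    rec$visual_fail, thresholds)
  rec$qc_result <- ifelse(rec$quality_group == "Unacceptable",
                          "failed", "passed")
  by_ct <- summarise(group_by(rec, .data$cancer_type),
                     total_slides = n(),
                     failed_slides = sum(.data$qc_result == "failed"),
                     .groups = "drop")
  by_group <- count(rec, .data$quality_group, name = "n_slides",
                    .drop = FALSE)
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- write_qc_tables(
      wsi_list = wsi_list_records(rec$cancer_type, rec$wsi_id, rec$qc_result),
      visual_qc = visual_qc_records(
        rec$wsi_id, rec$num_nuclei, rec$size_mean, rec$size_std, rec$note,
        ifelse(rec$visual_fail, "1",
               ifelse(rec$qc_result == "failed", "1", "0")),
        rec$comment),
      region_check = region_check_records(rec$wsi_id, rec$num_bad,
                                          rec$num_sampled),
      dir = dir
    )
    summary_paths <- c(
      by_cancer_type = file.path(dir, "summary_by_cancer_type.csv"),
      by_group = file.path(dir, "summary_by_quality_group.csv")
    )
    write.csv(as.data.frame(by_ct), summary_paths[["by_cancer_type"]],
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(by_group), summary_paths[["by_group"]],
              row.names = FALSE, quote = FALSE)
    paths <- c(paths, summary_paths)
  }
  invisible(list(records = rec, by_cancer_type = by_ct, by_group = by_group,
                 paths = paths))
}
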