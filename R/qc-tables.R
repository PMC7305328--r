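#' Quality-control record tables
#'
#' Three tables accompany a released segmentation dataset:
#'
#' * the **WSI list** — one row per slide with its cancer-type code and the
#'   summarized QC verdict (`passed` / `failed`);
#' * the **visual QC table** — slides selected for visual assessment, with
#'   per-slide nucleus count, mean and standard deviation of nuclear size
#'   (pixels), the selection reason, the unacceptable flag (0 acceptable,
#'   1 unacceptable, `unknown` when not judged) and a free-text comment;
#' * the **region-checking table** — per slide, the number of randomly
#'   sampled regions that were visually judged and how many of them were
#'   unacceptable.
#'
#' The constructors validate the invariants (flag domains, `size_std = 0`
#' whenever fewer than two nuclei, unacceptable regions never exceeding
#' sampled regions) and return tibbles.
#'
#' @param cancer_type Short cancer-type codes (e.g. `"BLCA"`).
#' @param wsi_id Slide identifier strings.
#' @param qc_result `"passed"` or `"failed"` per slide.
#' @param num_nuclei Integer nucleus counts (>= 0).
#' @param size_mean,size_std Mean / standard deviation of nuclear size in
#'   pixels (>= 0).
#' @param note Free-text reason the slide was selected for assessment.
#' @param unacceptable_flag One of `0`, `1`, `"unknown"` per slide.
#' @param comment Free-text assessment comment.
#' @param num_unacceptable_regions,num_sampled_regions Integer counts per
#'   slide; sampled >= 1, unacceptable <= sampled.
#' @return A validated tibble.
#' @name qc_records
NULL

#' @rdname qc_records
#' @export
wsi_list_records <- function(cancer_type, wsi_id, qc_result) {
  x <- tibble(cancer_type = as.character(cancer_type),
              wsi_id = as.character(wsi_id),
              qc_result = as.character(qc_result))
  if (any(!nzchar(x$cancer_type))) abort("cancer_type must be non-empty.")
  bad <- setdiff(unique(x$qc_result), c("passed", "failed"))
  if (length(bad)) {
    abort(paste0("qc_result must be 'passed' or 'failed'; found: ",
                 paste(bad, collapse = ", "), "."))
  }
  x
}

#' @rdname qc_records
#' @export
visual_qc_records <- function(wsi_id, num_nuclei, size_mean, size_std,
                              note = "", unacceptable_flag = "unknown",
                              comment = "") {
  x <- tibble(wsi_id = as.character(wsi_id),
              num_nuclei = as.integer(num_nuclei),
              size_mean = as.numeric(size_mean),
              size_std = as.numeric(size_std),
              note = as.character(note),
              unacceptable_flag = as.character(unacceptable_flag),
              comment = as.character(comment))
  bad <- setdiff(unique(x$unacceptable_flag), c("0", "1", "unknown"))
  if (length(bad)) {
    abort(paste0("unacceptable_flag must be 0, 1 or 'unknown'; found: ",
                 paste(bad, collapse = ", "), "."))
  }
  if (any(x$num_nuclei < 0) || any(x$size_mean < 0) || any(x$size_std < 0)) {
    abort("num_nuclei, size_mean and size_std must be non-negative.")
  }
  if (any(x$num_nuclei <= 1 & x$size_std != 0)) {
    abort("size_std must be 0 when num_nuclei <= 1.")
  }
  x
}

#' @rdname qc_records
#' @export
region_check_records <- function(wsi_id, num_unacceptable_regions,
                                 num_sampled_regions) {
  x <- tibble(wsi_id = as.character(wsi_id),
              num_unacceptable_regions = as.integer(num_unacceptable_regions),
              num_sampled_regions = as.integer(num_sampled_regions))
  if (any(x$num_sampled_regions < 1)) {
    abort("num_sampled_regions must be >= 1.")
  }
  if (any(x$num_unacceptable_regions > x$num_sampled_regions) ||
      any(x$num_unacceptable_regions < 0)) {
    abort("num_unacceptable_regions must lie in [0, num_sampled_regions].")
  }
  x
}

# space-free headers; the released-data field names use spaces in prose
.qc_headers <- list(
  wsi_list = c(cancer_type = "CancerType", wsi_id = "WsiId",
               qc_result = "QcResult"),
  visual_qc = c(wsi_id = "WsiId", num_nuclei = "NumNucleiSample",
                size_mean = "SizeOfNucleiAverage",
                size_std = "SizeOfNucleiStddev", note = "Note",
                unacceptable_flag = "SegmentationUnacceptableOrNot",
                comment = "VisualAssessmentComment"),
  region_check = c(wsi_id = "WsiId",
                   num_unacceptable_regions = "NumOfUnacceptableSegRegions",
                   num_sampled_regions = "NumOfSampledRegions")
)

.qc_files <- c(wsi_list = "wsi_list.csv", visual_qc = "visual_qc.csv",
               region_check = "region_check.csv")

#' Write and read the three QC CSV tables
#'
#' `write_qc_tables()` materializes the WSI list, visual QC and
#' region-checking tables (see [qc_records]) as CSV files with stable,
#' space-free column headers. The unknown visual-QC flag is serialized as
#' `"?"`. `read_qc_tables()` is its inverse.
#'
#' @param wsi_list,visual_qc,region_check Record tibbles from the
#'   [qc_records] constructors; any may be `NULL` to skip.
#' @param dir Destination / source directory.
#' @return `write_qc_tables()` returns the written paths (named character
#'   vector) invisibly; `read_qc_tables()` returns a named list of tibbles.
#' @export
write_qc_tables <- function(wsi_list = NULL, visual_qc = NULL,
                            region_check = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(tab, kind) {
    out <- as.data.frame(tab)
    if (kind == "visual_qc") {
      out$unacceptable_flag[out$unacceptable_flag == "unknown"] <- "?"
    }
    names(out) <- unname(.qc_headers[[kind]][names(out)])
    p <- file.path(dir, .qc_files[[kind]])
    write.csv(out, p, row.names = FALSE)
    p
  }
  if (!is.null(wsi_list)) {
    paths["wsi_list"] <- emit(do.call(wsi_list_records, as.list(wsi_list)),
                              "wsi_list")
  }
  if (!is.null(visual_qc)) {
    paths["visual_qc"] <- emit(do.call(visual_qc_records, as.list(visual_qc)),
                               "visual_qc")
  }
  if (!is.null(region_check)) {
    paths["region_check"] <- emit(do.call(region_check_records,
                                          as.list(region_check)),
                                  "region_check")
  }
  invisible(paths)
}

#' @rdname write_qc_tables
#' @export
read_qc_tables <- function(dir = ".") {
  out <- list()
  for (kind in names(.qc_files)) {
    p <- file.path(dir, .qc_files[[kind]])
    if (!file.exists(p)) next
    raw <- read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
    hdr <- .qc_headers[[kind]]
    if (!identical(names(raw), unname(hdr))) {
      abort(paste0("Unexpected header in ", p, ": ",
                   paste(names(raw), collapse = ", ")))
    }
    names(raw) <- names(hdr)
    if (kind == "visual_qc") {
      raw$unacceptable_flag[raw$unacceptable_flag == "?"] <- "unknown"
    }
    out[[kind]] <- switch(kind,
      wsi_list = do.call(wsi_list_records, as.list(raw)),
      visual_qc = do.call(visual_qc_records, as.list(raw)),
      region_check = do.call(region_check_records, as.list(raw)))
  }
  out
}
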