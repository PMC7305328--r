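#' Evaluate one predicted patch against ground truth
#'
#' Applies the central crop to both masks, then computes the per-patch
#' metric bundle: pixel Dice of the binarized masks, Instance-Dice, object
#' precision/recall, and the two nuclei counts whose sum is the patch's
#' aggregation weight.
#'
#' @param gt,pred Instance label matrices of identical shape.
#' @param crop_size Central evaluation window, default 226; `NULL` skips
#'   cropping.
#' @param iou_threshold Object-match threshold for precision/recall.
#' @return A one-row tibble: `dice`, `instance_dice`, `gt_count`,
#'   `pred_count`, `weight`, `precision`, `recall`.
#' @export
evaluate_patch <- function(gt, pred, crop_size = 226, iou_threshold = 0.5) {
  if (!all(dim(gt) == dim(pred))) abort("Masks must share the same shape.")
  storage.mode(gt) <- "integer"
  storage.mode(pred) <- "integer"
  if (!is.null(crop_size)) {
    gt <- central_crop(gt, crop_size)
    pred <- central_crop(pred, crop_size)
  }
  t_n <- length(unique(gt[gt > 0]))
  p_n <- length(unique(pred[pred > 0]))
  pr <- object_precision_recall(gt, pred, iou_threshold)
  tibble(
    dice = pixel_dice(gt, pred),
    instance_dice = instance_dice(gt, pred),
    gt_count = t_n, pred_count = p_n, weight = t_n + p_n,
    precision = pr$precision, recall = pr$recall
  )
}

#' Evaluate a set of patches
#'
#' Runs [evaluate_patch()] over paired lists of ground-truth and predicted
#' masks and aggregates with the package's dataset conventions: Dice and
#' Instance-Dice are nuclei-count-weighted means over patches where they are
#' defined, counts feed MAE% and the Pearson correlation, and patches with
#' undefined metrics (no truth and no prediction) are excluded from the
#' aggregates but counted.
#'
#' @param gt_masks,pred_masks Equal-length lists of label matrices.
#' @param crop_size,iou_threshold Passed to [evaluate_patch()].
#' @param patch_ids Optional identifier vector for the per-patch table.
#' @return An object of class `"dataset_evaluation"`: a list with `patches`
#'   (per-patch tibble) and `summary` (one-row tibble). Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
evaluate_patches <- function(gt_masks, pred_masks, crop_size = 226,
                             iou_threshold = 0.5, patch_ids = NULL) {
  if (length(gt_masks) != length(pred_masks) || !length(gt_masks)) {
    abort("`gt_masks` and `pred_masks` must be equal-length, non-empty lists.")
  }
  patch_ids <- patch_ids %||% sprintf("patch_%04d", seq_along(gt_masks))
  per <- purrr::map2(gt_masks, pred_masks, evaluate_patch,
                     crop_size = crop_size, iou_threshold = iou_threshold)
  patches <- mutate(dplyr::bind_rows(per), patch_id = patch_ids,
                    .before = 1)
  structure(list(patches = patches, summary = summarise_patches(patches)),
            class = "dataset_evaluation")
}

summarise_patches <- function(patches) {
  w <- patches$weight
  idice_keep <- w > 0 & !is.na(patches$instance_dice)
  tibble(
    n_patches = nrow(patches),
    n_undefined = sum(w == 0),
    weighted_dice = weighted_dataset_dice(patches),
    instance_dice = if (any(idice_keep)) {
      sum(patches$instance_dice[idice_keep] * w[idice_keep]) / sum(w[idice_keep])
    } else NA_real_,
    pearson_r = if (nrow(patches) >= 2) {
      pearson_count_correlation(patches$pred_count, patches$gt_count)
    } else NA_real_,
    mae_percent = mae_percent(patches$pred_count, patches$gt_count),
    mean_precision = mean(patches$precision),
    mean_recall = mean(patches$recall)
  )
}

#' @export
print.dataset_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<dataset_evaluation> ", s$n_patches, " patches (",
      s$n_undefined, " with undefined Dice)\n", sep = "")
  cat(sprintf("  weighted Dice  %.3f\n  Instance-Dice  %.3f\n", s$weighted_dice,
              s$instance_dice))
  cat(sprintf("  count r        %.3f\n  MAE%%           %.1f\n", s$pearson_r,
              s$mae_percent))
  invisible(x)
}

#' Tidy / glance methods for dataset evaluations
#'
#' `tidy()` returns the per-patch metric table; `glance()` returns the
#' one-row aggregate summary.
#'
#' @param x A `dataset_evaluation` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dataset_evaluation
#' @export
tidy.dataset_evaluation <- function(x, ...) x$patches

#' @rdname tidy.dataset_evaluation
#' @method glance dataset_evaluation
#' @export
glance.dataset_evaluation <- function(x, ...) x$summary

#' Plot a dataset evaluation
#'
#' Scatter of predicted vs. ground-truth nuclei counts per patch, with the
#' identity line and the Pearson correlation in the subtitle — the standard
#' count-agreement picture for a segmentation run.
#'
#' @param object A `dataset_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dataset_evaluation
#' @export
autoplot.dataset_evaluation <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$patches,
                  ggplot2::aes(x = .data$gt_count, y = .data$pred_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Ground-truth nuclei count", y = "Predicted nuclei count",
      title = "Predicted vs. ground-truth nuclei counts",
      subtitle = sprintf("Pearson r = %.3f, MAE%% = %.1f over %d patches",
                         s$pearson_r, s$mae_percent, s$n_patches)
    ) +
    ggplot2::theme_minimal()
}

#' Display a synthetic patch and its ground truth
#'
#' Three-panel ggplot: rendered H&E-like image, instance mask (random
#' colors), and the two model-output maps overlaid (probability as fill,
#' detected centers as contours).
#'
#' @param object A `synth_patch` from [generate_patch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synth_patch
#' @export
autoplot.synth_patch <- function(object, ...) {
  patch <- object
  h <- nrow(patch$truth_mask)
  # column-major to match as.vector() on matrices: y varies fastest
  df <- tidyr::expand_grid(x = seq_len(ncol(patch$truth_mask)), y = seq_len(h))
  df$label <- as.vector(patch$truth_mask)
  df$prob <- as.vector(patch$prob_map)
  df$det <- as.vector(patch$det_map)
  df$rgb <- grDevices::rgb(as.vector(patch$image[, , 1]),
                           as.vector(patch$image[, , 2]),
                           as.vector(patch$image[, , 3]))
  long <- dplyr::bind_rows(
    mutate(df, panel = "image", fill = .data$rgb),
    mutate(df, panel = "instances",
           fill = ifelse(.data$label == 0, "#f0f0f0",
                         grDevices::hcl(h = (.data$label * 47) %% 360, c = 60,
                                        l = 60))),
    mutate(df, panel = "probability map",
           fill = grDevices::gray(1 - .data$prob))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
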