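#' Central crop of a mask or map
#'
#' Evaluation uses only the central window of each patch (226 x 226 of a
#' 256 x 256 patch by default), because segmentation near patch borders is
#' ambiguous: nuclei there are cut off by the field of view. The window is
#' anchored at `floor((size - crop) / 2)` in each dimension. For integer
#' label masks, instances are clipped, instances falling entirely outside
#' the window disappear, and surviving labels are renumbered consecutively;
#' real-valued maps and RGB arrays are cropped as-is.
#'
#' @param x Matrix (label mask or map) or `[row, col, channel]` array.
#' @param crop_size Window edge length, default 226.
#' @return The cropped object, same type as `x`.
#' @export
central_crop <- function(x, crop_size = 226) {
  d <- dim(x)
  if (crop_size > d[1] || crop_size > d[2]) {
    abort("`crop_size` exceeds the input dimensions.")
  }
  r0 <- floor((d[1] - crop_size) / 2)
  c0 <- floor((d[2] - crop_size) / 2)
  rows <- (r0 + 1):(r0 + crop_size)
  cols <- (c0 + 1):(c0 + crop_size)
  if (length(d) == 3) return(x[rows, cols, , drop = FALSE])
  out <- x[rows, cols, drop = FALSE]
  if (is.integer(x)) relabel_consecutive(out) else out
}

#' Pixel-level Dice coefficient
#'
#' `2|A & B| / (|A| + |B|)` over binary masks — the class-level overlap of
#' nuclear material. Undefined (`NA`) when both masks are empty.
#'
#' @param a,b Binary (logical or 0/1) matrices of identical shape.
#' @return A number in `[0, 1]`, or `NA_real_` when both masks are empty.
#' @export
pixel_dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("Masks must share the same shape.")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' Nuclei-count-weighted dataset Dice
#'
#' Per-patch Dice scores are averaged with weights `t + p` (ground-truth
#' plus predicted nuclei count of the patch), which keeps patches where Dice
#' is ill-defined — no ground truth and no prediction, weight 0 — from
#' diluting the aggregate while emphasizing patches that actually contain
#' nuclei.
#'
#' @param evals A tibble with columns `dice`, `gt_count`, `pred_count`
#'   (e.g. from [evaluate_patches()]).
#' @return The weighted mean Dice, or `NA_real_` if every weight is zero.
#' @export
weighted_dataset_dice <- function(evals) {
  w <- evals$gt_count + evals$pred_count
  keep <- w > 0 & !is.na(evals$dice)
  if (!any(keep)) return(NA_real_)
  sum(evals$dice[keep] * w[keep]) / sum(w[keep])
}

# cross-tabulate pixel overlaps between two label masks; rows = gt labels,
# cols = pred labels (label values as dimnames), background excluded
overlap_table <- function(gt, pred) {
  sel <- gt > 0 | pred > 0
  table(gt = factor(gt[sel]), pred = factor(pred[sel]))
}

#' Instance-level Dice (ensemble form)
#'
#' Object-aware Dice that only credits overlap between matched objects:
#' every ground-truth object is paired with the predicted object it overlaps
#' most (and vice versa), each matched pair's intersection is counted once,
#' and the score is `2 * sum(matched intersections) / (sum of all GT object
#' sizes + sum of all predicted object sizes)`. Splitting or merging nuclei
#' therefore costs score even when the binary foreground is perfect, which
#' is what makes the metric sensitive to instance separation quality.
#'
#' `method = "aggregated"` instead averages per-object Dice values of the
#' best-overlap pairs (an alternative definition in circulation); the
#' ensemble form is the default used everywhere in this package.
#'
#' @param gt,pred Instance label matrices of identical shape.
#' @param method `"ensemble"` (default) or `"aggregated"`.
#' @return A number in `[0, 1]`, or `NA_real_` when both maps are empty.
#' @export
instance_dice <- function(gt, pred, method = c("ensemble", "aggregated")) {
  method <- match.arg(method)
  if (!all(dim(gt) == dim(pred))) abort("Masks must share the same shape.")
  gt_sizes <- tabulate(gt[gt > 0])
  pred_sizes <- tabulate(pred[pred > 0])
  gt_sizes <- gt_sizes[gt_sizes > 0]
  pred_sizes <- pred_sizes[pred_sizes > 0]
  if (!length(gt_sizes) && !length(pred_sizes)) return(NA_real_)
  if (!length(gt_sizes) || !length(pred_sizes)) {
    return(if (method == "ensemble") 0 else 0)
  }
  ov <- overlap_table(gt, pred)
  ov <- ov[rownames(ov) != "0", colnames(ov) != "0", drop = FALSE]
  ov <- ov[order(as.integer(rownames(ov))), order(as.integer(colnames(ov))),
           drop = FALSE]
  if (!length(ov) || sum(ov) == 0) return(0)
  # best partner per gt object and per pred object (ties -> smallest label);
  # each matched (g, p) pair's intersection counted once
  g_best <- apply(ov, 1, which.max)
  p_best <- apply(ov, 2, which.max)
  pairs <- unique(rbind(
    cbind(seq_len(nrow(ov)), g_best),
    cbind(p_best, seq_len(ncol(ov)))
  ))
  inter <- ov[pairs]
  if (method == "aggregated") {
    g_sz <- gt_sizes[as.integer(rownames(ov))[pairs[, 1]]]
    p_sz <- pred_sizes[as.integer(colnames(ov))[pairs[, 2]]]
    d <- 2 * inter / (g_sz + p_sz)
    return(mean(d))
  }
  2 * sum(inter) / (sum(gt_sizes) + sum(pred_sizes))
}

#' Object-level precision and recall
#'
#' Computable surrogate for the visual "both precision and recall at least
#' 75%" region judgment: ground-truth and predicted objects are matched
#' one-to-one greedily by descending IoU, pairs with IoU at or above
#' `iou_threshold` count as true positives, and precision / recall follow.
#' Conventions for empty maps: both empty gives (1, 1); empty prediction
#' against non-empty truth gives (1, 0); non-empty prediction against empty
#' truth gives (0, 1).
#'
#' @param gt,pred Instance label matrices of identical shape.
#' @param iou_threshold Match threshold in `(0, 1]`, default 0.5.
#' @return A one-row tibble with `precision`, `recall`, `tp`, `gt_count`,
#'   `pred_count`.
#' @export
object_precision_recall <- function(gt, pred, iou_threshold = 0.5) {
  if (!all(dim(gt) == dim(pred))) abort("Masks must share the same shape.")
  if (iou_threshold <= 0 || iou_threshold > 1) {
    abort("`iou_threshold` must lie in (0, 1].")
  }
  gt_sizes <- tabulate(gt[gt > 0])
  pred_sizes <- tabulate(pred[pred > 0])
  n_gt <- sum(gt_sizes > 0)
  n_pred <- sum(pred_sizes > 0)
  if (n_gt == 0 && n_pred == 0) {
    return(tibble(precision = 1, recall = 1, tp = 0L,
                  gt_count = 0L, pred_count = 0L))
  }
  if (n_pred == 0) {
    return(tibble(precision = 1, recall = 0, tp = 0L,
                  gt_count = n_gt, pred_count = 0L))
  }
  if (n_gt == 0) {
    return(tibble(precision = 0, recall = 1, tp = 0L,
                  gt_count = 0L, pred_count = n_pred))
  }
  ov <- overlap_table(gt, pred)
  ov <- ov[rownames(ov) != "0", colnames(ov) != "0", drop = FALSE]
  ov <- ov[order(as.integer(rownames(ov))), order(as.integer(colnames(ov))),
           drop = FALSE]
  g_lab <- as.integer(rownames(ov))
  p_lab <- as.integer(colnames(ov))
  iou <- matrix(0, nrow(ov), ncol(ov))
  for (j in seq_len(ncol(ov))) {
    inter <- as.numeric(ov[, j])
    uni <- gt_sizes[g_lab] + pred_sizes[p_lab[j]] - inter
    iou[, j] <- inter / uni
  }
  tp <- 0L
  g_used <- rep(FALSE, nrow(iou)); p_used <- rep(FALSE, ncol(iou))
  repeat {
    iou_live <- iou
    iou_live[g_used, ] <- -1
    iou_live[, p_used] <- -1
    best <- which.max(iou_live)
    if (!length(best) || iou_live[best] < iou_threshold) break
    gi <- (best - 1) %% nrow(iou) + 1
    pj <- (best - 1) %/% nrow(iou) + 1
    g_used[gi] <- TRUE; p_used[pj] <- TRUE
    tp <- tp + 1L
    if (all(g_used) || all(p_used)) break
  }
  tibble(precision = tp / n_pred, recall = tp / n_gt, tp = tp,
         gt_count = n_gt, pred_count = n_pred)
}

#' Mean absolute error ratio of nuclei counts (MAE%)
#'
#' `mean(|p - t|) / mean(t)` over patches, reported as a percentage — the
#' average absolute count error relative to the average true count. Because
#' both means share the patch count, this equals `sum(|p - t|) / sum(t)`.
#'
#' @param p Predicted nuclei counts per patch.
#' @param t Ground-truth nuclei counts per patch.
#' @return MAE as a percentage, or `NA_real_` when `sum(t) == 0`.
#' @examples
#' mae_percent(c(15, 25), c(20, 20))  # 25
#' @export
mae_percent <- function(p, t) {
  if (length(p) != length(t) || length(t) < 1) {
    abort("`p` and `t` must be equal-length, non-empty count vectors.")
  }
  if (sum(t) == 0) return(NA_real_)
  100 * sum(abs(p - t)) / sum(t)
}

#' Pearson correlation of predicted vs. true nuclei counts
#'
#' @param p,t Equal-length count vectors (length >= 2).
#' @return Pearson's r, or `NA_real_` when either vector is constant.
#' @export
pearson_count_correlation <- function(p, t) {
  if (length(p) != length(t) || length(t) < 2) {
    abort("`p` and `t` must be equal-length vectors of length >= 2.")
  }
  if (sd(p) == 0 || sd(t) == 0) return(NA_real_)
  cor(p, t)
}
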