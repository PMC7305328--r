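# Independent brute-force reference implementations used to lock the metric
# definitions. Deliberately written as plain loops over objects/pixels,
# sharing no code with the package internals.

oracle_pixel_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    ai <- a[i] > 0; bi <- b[i] > 0
    na <- na + ai; nb <- nb + bi
    inter <- inter + (ai && bi)
  }
  if (na + nb == 0) return(NA_real_)
  2 * inter / (na + nb)
}

# ensemble instance dice: best-overlap partner for each object in either
# direction, matched intersections counted once
oracle_instance_dice <- function(gt, pred) {
  gl <- sort(unique(gt[gt > 0])); pl <- sort(unique(pred[pred > 0]))
  if (!length(gl) && !length(pl)) return(NA_real_)
  if (!length(gl) || !length(pl)) return(0)
  inter <- matrix(0, length(gl), length(pl))
  for (gi in seq_along(gl)) for (pj in seq_along(pl)) {
    inter[gi, pj] <- sum(gt == gl[gi] & pred == pl[pj])
  }
  pair_keys <- character(0)
  total <- 0
  for (gi in seq_along(gl)) {
    best <- 1
    for (pj in seq_along(pl)) if (inter[gi, pj] > inter[gi, best]) best <- pj
    key <- paste(gi, best)
    if (!key %in% pair_keys) {
      pair_keys <- c(pair_keys, key)
      total <- total + inter[gi, best]
    }
  }
  for (pj in seq_along(pl)) {
    best <- 1
    for (gi in seq_along(gl)) if (inter[gi, pj] > inter[best, pj]) best <- gi
    key <- paste(best, pj)
    if (!key %in% pair_keys) {
      pair_keys <- c(pair_keys, key)
      total <- total + inter[best, pj]
    }
  }
  2 * total / (sum(gt > 0) + sum(pred > 0))
}

# greedy IoU matching, scanning ties in (gt index fastest, pred index outer)
# order to mirror column-major which.max
oracle_precision_recall <- function(gt, pred, thr = 0.5) {
  gl <- sort(unique(gt[gt > 0])); pl <- sort(unique(pred[pred > 0]))
  if (!length(gl) && !length(pl)) return(c(precision = 1, recall = 1))
  if (!length(pl)) return(c(precision = 1, recall = 0))
  if (!length(gl)) return(c(precision = 0, recall = 1))
  iou <- matrix(0, length(gl), length(pl))
  for (gi in seq_along(gl)) for (pj in seq_along(pl)) {
    inter <- sum(gt == gl[gi] & pred == pl[pj])
    uni <- sum(gt == gl[gi] | pred == pl[pj])
    iou[gi, pj] <- inter / uni
  }
  used_g <- rep(FALSE, length(gl)); used_p <- rep(FALSE, length(pl))
  tp <- 0
  repeat {
    best <- -1; bg <- 0; bp <- 0
    for (pj in seq_along(pl)) for (gi in seq_along(gl)) {
      if (!used_g[gi] && !used_p[pj] && iou[gi, pj] > best) {
        best <- iou[gi, pj]; bg <- gi; bp <- pj
      }
    }
    if (best < thr || bg == 0) break
    used_g[bg] <- TRUE; used_p[bp] <- TRUE
    tp <- tp + 1
  }
  c(precision = tp / length(pl), recall = tp / length(gl))
}

oracle_mae_percent <- function(p, t) {
  100 * mean(abs(p - t)) / mean(t)
}

# random label map with a few blobby objects (labels need not be connected;
# the metrics are set arithmetic over labels)
random_label_map <- function(n = 16, max_labels = 4) {
  matrix(sample(0:max_labels, n * n, replace = TRUE,
                prob = c(0.6, rep(0.4 / max_labels, max_labels))),
         n, n)
}

# tiny analytic model-output pair: disks with gaussian center bumps
disk_pair <- function(size, centers, radius) {
  prob <- matrix(0, size, size)
  det <- matrix(0, size, size)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
    prob[d2 <= radius^2] <- 0.9
    det <- pmax(det, exp(-d2 / (2 * (radius / 2)^2)))
  }
  list(prob_map = prob, det_map = det)
}
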