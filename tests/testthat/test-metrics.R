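test_that("central crop anchors, clips and renumbers", {
  z <- matrix(0L, 256, 256)
  expect_identical(central_crop(z), matrix(0L, 226, 226))
  expect_error(central_crop(matrix(0L, 100, 100), 226), "exceeds")

  # a nucleus wholly inside the center is untouched
  m <- matrix(0L, 256, 256); m[100:110, 100:110] <- 1L
  expect_equal(sum(central_crop(m) > 0), 121)

  # a nucleus straddling the window is clipped to the exact intersection
  m2 <- matrix(0L, 256, 256)
  m2[1:10, 1:10] <- 1L              # fully outside (window starts at 16)
  m2[14:18, 120:130] <- 2L          # straddles the top edge
  cc <- central_crop(m2)
  off <- floor((256 - 226) / 2)     # = 15
  brute <- sum(m2[(off + 1):(off + 226), (off + 1):(off + 226)] == 2L)
  expect_equal(sum(cc > 0), brute)
  expect_setequal(unique(as.vector(cc)), c(0L, 1L))  # renumbered from 2 -> 1
})

test_that("pixel dice matches hand counts and handles emptiness", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  expect_true(is.na(pixel_dice(a, b)))
  a[1, 1:4] <- 1L; b[1, 1:4] <- 1L
  expect_equal(pixel_dice(a, b), 1)
  b2 <- matrix(0L, 4, 4); b2[3, 1:4] <- 1L
  expect_equal(pixel_dice(a, b2), 0)
  b3 <- matrix(0L, 4, 4); b3[1, 3:4] <- 1L; b3[2, 1:2] <- 1L
  expect_equal(pixel_dice(a, b3), 0.5)  # |a|=4, |b|=4, overlap 2
  expect_error(pixel_dice(a, matrix(0L, 3, 3)), "shape")
})

test_that("weighted dataset dice follows the nuclei-count weighting", {
  evals <- tibble::tibble(dice = c(1.0, 0.5), gt_count = c(3, 1),
                          pred_count = c(3, 1))
  expect_equal(weighted_dataset_dice(evals), 0.875)  # (6*1 + 2*0.5)/8

  # constancy and symmetry
  ev2 <- tibble::tibble(dice = rep(0.7, 5), gt_count = 1:5, pred_count = 0:4)
  expect_equal(weighted_dataset_dice(ev2), 0.7)
  ev3 <- tibble::tibble(dice = c(0.2, 0.4, 0.9), gt_count = c(2, 2, 2),
                        pred_count = c(2, 2, 2))
  expect_equal(weighted_dataset_dice(ev3), mean(ev3$dice))

  # zero-weight patches are excluded; all-zero weight is undefined
  ev4 <- tibble::tibble(dice = c(NA, 1), gt_count = c(0, 2), pred_count = c(0, 2))
  expect_equal(weighted_dataset_dice(ev4), 1)
  ev5 <- tibble::tibble(dice = NA_real_, gt_count = 0, pred_count = 0)
  expect_true(is.na(weighted_dataset_dice(ev5)))
})

test_that("instance dice agrees with the brute-force oracle and bounds", {
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L; m[6:8, 5:8] <- 2L
  expect_equal(instance_dice(m, m), 1)
  perm <- m; perm[m == 1L] <- 2L; perm[m == 2L] <- 1L
  expect_equal(instance_dice(m, perm), 1)  # labeling-invariant

  # two GT objects merged into one predicted object
  merged <- (m > 0) * 1L
  expect_equal(instance_dice(m, merged), oracle_instance_dice(m, merged))

  withr::with_seed(101, {
    for (i in 1:50) {
      gt <- random_label_map(); pred <- random_label_map()
      id <- instance_dice(gt, pred)
      expect_equal(id, oracle_instance_dice(gt, pred))
      pd <- pixel_dice(gt, pred)
      if (!is.na(id) && !is.na(pd)) expect_lte(id, pd + 1e-12)
    }
  })
})

test_that("object precision/recall uses greedy IoU matching and empty-map conventions", {
  m <- matrix(0L, 16, 16)
  m[1:3, 1:3] <- 1L; m[6:8, 6:8] <- 2L; m[11:13, 1:3] <- 3L; m[11:13, 11:13] <- 4L
  pr <- object_precision_recall(m, m)
  expect_equal(c(pr$precision, pr$recall), c(1, 1))

  miss1 <- m; miss1[m == 4L] <- 0L  # one of four GT nuclei missed
  pr2 <- object_precision_recall(m, miss1)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 0.75))

  z <- matrix(0L, 16, 16)
  expect_equal(unlist(object_precision_recall(z, z)[, c("precision", "recall")]),
               c(precision = 1, recall = 1))
  expect_equal(unlist(object_precision_recall(m, z)[, c("precision", "recall")]),
               c(precision = 1, recall = 0))
  expect_equal(unlist(object_precision_recall(z, m)[, c("precision", "recall")]),
               c(precision = 0, recall = 1))
  expect_error(object_precision_recall(m, m, iou_threshold = 0), "iou_threshold")

  withr::with_seed(202, {
    for (i in 1:50) {
      gt <- random_label_map(); pred <- random_label_map()
      got <- object_precision_recall(gt, pred)
      want <- oracle_precision_recall(gt, pred)
      expect_equal(c(got$precision, got$recall), unname(want))
    }
  })
})

test_that("MAE% uses the ratio-of-means aggregation", {
  expect_equal(mae_percent(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(mae_percent(c(15, 25), c(20, 20)), 25)  # (5+5)/40
  expect_equal(mae_percent(10, 20), 50)
  expect_true(is.na(mae_percent(c(1, 2), c(0, 0))))
  # scale invariance
  withr::with_seed(7, {
    p <- sample(10:60, 20, TRUE); t <- sample(10:60, 20, TRUE)
    expect_equal(mae_percent(3 * p, 3 * t), mae_percent(p, t))
    expect_equal(mae_percent(p, t), oracle_mae_percent(p, t))
  })
})

test_that("count correlation matches an independent computation", {
  t <- c(3, 9, 14, 20, 31)
  expect_equal(pearson_count_correlation(t, t), 1)
  expect_equal(pearson_count_correlation(-t + 50, t), -1)
  expect_true(is.na(pearson_count_correlation(rep(5, 5), t)))
  withr::with_seed(8, {
    p <- rnorm(40); q <- rnorm(40)
    # textbook formula evaluated independently
    r_ref <- sum((p - mean(p)) * (q - mean(q))) /
      sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
    expect_equal(pearson_count_correlation(p, q), r_ref, tolerance = 1e-12)
  })
})

test_that("dataset evaluation aggregates, tidies and plots", {
  gt <- lapply(c(61, 62), function(s) {
    generate_instance_mask(synth_config(seed = s))
  })
  ev <- evaluate_patches(gt, gt, crop_size = 226)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(tidy(ev)), 2)
  g <- glance(ev)
  expect_equal(g$weighted_dice, 1)
  expect_equal(g$instance_dice, 1)
  expect_equal(g$mae_percent, 0)
  expect_s3_class(autoplot(ev), "ggplot")
  # weighted dice lies between per-patch extremes on degraded input
  deg <- lapply(gt, function(m) {
    s <- segment_instances(pair = derive_model_maps(
      m, corruption_config(fn_rate = 0.3, seed = 99)))
    s
  })
  ev2 <- evaluate_patches(gt, deg)
  td <- tidy(ev2)
  expect_gte(glance(ev2)$weighted_dice, min(td$dice))
  expect_lte(glance(ev2)$weighted_dice, max(td$dice))
})
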