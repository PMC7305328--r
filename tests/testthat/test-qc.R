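test_that("sampled region locations are in-bounds, distinct and reproducible", {
  loc <- sample_patch_locations(10000, 8000, seed = 3)
  expect_equal(nrow(loc), 15)
  expect_true(all(loc$x >= 0 & loc$x <= 10000 - 256))
  expect_true(all(loc$y >= 0 & loc$y <= 8000 - 256))
  expect_false(any(duplicated(loc)))
  expect_identical(loc, sample_patch_locations(10000, 8000, seed = 3))
  expect_error(sample_patch_locations(200, 500), "smaller")
})

test_that("sampled origins are uniform over the slide", {
  loc <- sample_patch_locations(1000, 1000, n = 4000, seed = 12)
  gx <- cut(loc$x, breaks = seq(0, 1000 - 256 + 1, length.out = 5),
            include.lowest = TRUE)
  gy <- cut(loc$y, breaks = seq(0, 1000 - 256 + 1, length.out = 5),
            include.lowest = TRUE)
  p <- suppressWarnings(stats::chisq.test(table(gx, gy))$p.value)
  expect_gt(p, 0.01)
})

test_that("region adequacy is inclusive at the 75% boundary", {
  expect_true(patch_adequate(0.75, 0.75))
  expect_false(patch_adequate(1.0, 0.74))
  expect_false(patch_adequate(0.74, 1.0))
  expect_equal(patch_adequate(c(0.8, 0.6), c(0.9, 0.9)), c(TRUE, FALSE))
})

test_that("quality groups follow the bad-region breakpoints of 15 samples", {
  got <- classify_wsi(0:4, 15)
  expect_equal(as.character(got),
               c("Best", "Good", "Adequate", "Problematic", "Unacceptable"))
  expect_equal(as.character(classify_wsi(0, 15, visual_fail = TRUE)),
               "Unacceptable")
  expect_equal(as.character(classify_wsi(5:15, 15)),
               rep("Unacceptable", 11))
  expect_error(classify_wsi(16, 15), "num_bad")
  # generalizes to other denominators via the percentage cut points
  expect_equal(as.character(classify_wsi(c(0, 1, 2), 30)),
               c("Best", "Good", "Good"))
  expect_equal(as.character(classify_wsi(2, 10)), "Problematic")   # 20% inclusive
  expect_equal(as.character(classify_wsi(3, 10)), "Unacceptable")  # 30% > 20%
})

test_that("more bad regions never improve the quality group", {
  for (n in c(10, 15, 20)) {
    ranks <- as.integer(classify_wsi(0:n, n))
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("slide acceptability is inclusive at 80%", {
  expect_true(slide_acceptable(0.80))
  expect_false(slide_acceptable(0.79))
  expect_true(slide_acceptable(1.0))
})

test_that("per-slide statistics use the population standard deviation", {
  expect_equal(unlist(compute_wsi_statistics(c(10, 10, 10))),
               c(num_nuclei = 3, size_mean = 10, size_std = 0))
  expect_equal(unlist(compute_wsi_statistics(c(4, 8))),
               c(num_nuclei = 2, size_mean = 6, size_std = 2))
  expect_equal(unlist(compute_wsi_statistics(numeric())),
               c(num_nuclei = 0, size_mean = 0, size_std = 0))
  rec <- nucleus_records(c(4L, 8L), list(
    cbind(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0)),
    cbind(x = c(0, 0, 3, 3), y = c(0, 1, 1, 0))))
  expect_equal(compute_wsi_statistics(rec)$size_mean, 6)
})

test_that("outlier selection flags the extreme tails by rank within cancer type", {
  stats <- tibble::tibble(
    wsi_id = sprintf("w%03d", 1:100), cancer_type = "BLCA",
    num_nuclei = 1:100, size_mean = 50, size_std = 10)
  sel <- select_outlier_wsis(stats)
  expect_setequal(sel$wsi_id[sel$reason == "count_low"], c("w001", "w002"))
  expect_setequal(sel$wsi_id[sel$reason == "count_high"], c("w099", "w100"))
  # constant statistics fall back to the wsi_id tie-break, still ceil(0.02 n)
  expect_equal(sum(sel$reason == "size_low"), 2)

  esc <- select_outlier_wsis(stats, escalate = TRUE)  # another 2%, in total 4%
  expect_setequal(esc$wsi_id[esc$reason == "count_low"],
                  sprintf("w%03d", 1:4))
  expect_setequal(esc$wsi_id[esc$reason == "count_high"],
                  sprintf("w%03d", 97:100))

  one <- select_outlier_wsis(stats[1, ])
  expect_equal(nrow(one), 6)  # a singleton group lands in every tail
  expect_error(select_outlier_wsis(stats, tail_fraction = 0.6), "tail_fraction")
})

test_that("a strictly most-extreme slide is always selected", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      v <- sample(1000, n)
      stats <- tibble::tibble(wsi_id = sprintf("w%02d", seq_len(n)),
                              cancer_type = "GBM", num_nuclei = v,
                              size_mean = 1, size_std = 0)
      sel <- select_outlier_wsis(stats)
      expect_true(stats$wsi_id[which.max(v)] %in%
                    sel$wsi_id[sel$reason == "count_high"])
      expect_true(stats$wsi_id[which.min(v)] %in%
                    sel$wsi_id[sel$reason == "count_low"])
    }
  })
})

test_that("qc_report partitions slides into groups and writes consistent tables", {
  wsi_qc <- tibble::tibble(
    wsi_id = sprintf("s%d", 1:5), cancer_type = "LUAD",
    num_bad = 0:4, num_sampled = 15)
  d <- withr::local_tempdir()
  rep1 <- qc_report(wsi_qc, dir = d)
  expect_equal(as.character(rep1$records$quality_group),
               c("Best", "Good", "Adequate", "Problematic", "Unacceptable"))
  expect_equal(rep1$by_group$n_slides, rep(1L, 5))
  expect_equal(sum(rep1$by_group$n_slides), 5)
  expect_equal(rep1$by_cancer_type$failed_slides, 1)
  expect_true(all(file.exists(rep1$paths)))
  wl <- read_qc_tables(d)$wsi_list
  expect_equal(sum(wl$qc_result == "failed"), 1)

  # visual failure forces Unacceptable regardless of region counts
  all_fail <- dplyr::mutate(wsi_qc, visual_fail = TRUE)
  rep2 <- qc_report(all_fail)
  expect_true(all(rep2$records$quality_group == "Unacceptable"))
  expect_equal(sum(rep2$records$qc_result == "failed"), 5)
})

test_that("qc_report failure counts recount on randomized fixtures", {
  withr::with_seed(77, {
    n <- 200
    wsi_qc <- tibble::tibble(
      wsi_id = sprintf("r%03d", seq_len(n)),
      cancer_type = sample(c("BLCA", "BRCA", "GBM"), n, TRUE),
      num_bad = sample(0:15, n, TRUE), num_sampled = 15,
      visual_fail = runif(n) < 0.1)
    out <- qc_report(wsi_qc)
    recount <- sum(out$records$quality_group == "Unacceptable")
    expect_equal(sum(out$records$qc_result == "failed"), recount)
    expect_equal(sum(out$by_group$n_slides), n)
    expect_equal(sum(out$by_cancer_type$total_slides), n)
    expect_equal(sum(out$by_cancer_type$failed_slides), recount)
    # every slide lands in exactly one group
    expect_equal(nrow(out$records), n)
    expect_false(any(is.na(out$records$quality_group)))
  })
})
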