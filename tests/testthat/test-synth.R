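test_that("instance mask generation honors counts, disjointness and seeds", {
  cfg0 <- synth_config(nucleus_count_range = c(0, 0), seed = 3)
  expect_true(all(generate_instance_mask(cfg0) == 0))

  cfg <- synth_config(seed = 17)
  m1 <- generate_instance_mask(cfg)
  m2 <- generate_instance_mask(cfg)
  expect_identical(m1, m2)  # pure function of the seed

  k <- max(m1)
  expect_true(k >= cfg$nucleus_count_range[1] && k <= cfg$nucleus_count_range[2])
  expect_setequal(unique(as.vector(m1)), 0:k)  # labels exactly {0..K}
  nuc <- attr(m1, "nuclei")
  expect_equal(nrow(nuc), k)
  expect_equal(sum(nuc$area), sum(m1 > 0))  # one label per pixel
})

test_that("an infeasible configuration errors with the achieved count", {
  cfg <- synth_config(patch_size = 64, nucleus_count_range = c(60, 60),
                      radius_range = c(8, 10), seed = 1)
  expect_error(generate_instance_mask(cfg), "achieved")
})

test_that("rasterized areas track the analytic polygon area", {
  # Monte-Carlo: mean pixel-count area of the star polygons stays within
  # 15% of the mean shoelace area of the sampled vertex polygons
  areas_pix <- c(); areas_poly <- c()
  for (s in 1:200) {
    cfg <- synth_config(nucleus_count_range = c(20, 30),
                        radius_range = c(4, 10), seed = 1000 + s)
    m <- generate_instance_mask(cfg)
    k <- max(m)
    expect_true(k >= 20 && k <= 30)
    nuc <- attr(m, "nuclei")
    areas_pix <- c(areas_pix, nuc$area)
    areas_poly <- c(areas_poly, nuc$polygon_area)
  }
  expect_lt(abs(mean(areas_pix) - mean(areas_poly)) / mean(areas_poly), 0.15)
})

test_that("rendering separates stains and respects the mask", {
  cfg <- synth_config(noise_std = 0, blur_sigma = 0, seed = 5)
  m <- generate_instance_mask(cfg)
  img <- render_patch(m, cfg)
  cols <- unique(matrix(img, ncol = 3))
  expect_equal(nrow(cols), 2)  # exactly two colors, partitioned by the mask
  expect_equal(img[, , 1][m > 0], rep(cfg$nucleus_color[1], sum(m > 0)))

  # empty mask: uniform background (plus noise)
  cfg0 <- synth_config(nucleus_count_range = c(0, 0), seed = 5)
  img0 <- render_patch(generate_instance_mask(cfg0), cfg0)
  expect_lt(max(abs(img0[, , 1] - cfg0$background_color[1])), 0.25)

  # hematoxylin is darker: nuclear luminance below background, across seeds
  for (s in 1:60) {
    cfg_s <- synth_config(seed = s)
    m_s <- generate_instance_mask(cfg_s)
    img_s <- render_patch(m_s, cfg_s)
    lum <- 0.299 * img_s[, , 1] + 0.587 * img_s[, , 2] + 0.114 * img_s[, , 3]
    expect_lt(mean(lum[m_s > 0]), mean(lum[m_s == 0]))
  }
})

test_that("uncorrupted model maps reconstruct the mask exactly", {
  for (s in c(2, 23, 77)) {
    m <- generate_instance_mask(synth_config(seed = s))
    maps <- derive_model_maps(m, corruption_config(seed = s))
    expect_identical(maps$prob_map >= 0.5, m > 0)
    peaks <- EBImage::bwlabel((maps$det_map >= 0.99) * 1)
    expect_equal(max(peaks), max(m))  # one detection peak per nucleus
    expect_true(all(maps$prob_map >= 0 & maps$prob_map <= 1))
    expect_true(all(maps$det_map >= 0 & maps$det_map <= 1))
  }
})

test_that("full false-negative corruption empties both maps", {
  m <- generate_instance_mask(synth_config(seed = 9))
  maps <- derive_model_maps(m, corruption_config(fn_rate = 1, seed = 9))
  expect_true(all(maps$prob_map < 0.5))
  expect_true(all(maps$det_map < 0.5))
  expect_true(all(maps$provenance$erased))
})

test_that("erasure bookkeeping matches the binomial expectation", {
  cfg <- synth_config(nucleus_count_range = c(100, 100), radius_range = c(3, 5),
                      seed = 1)
  m <- generate_instance_mask(cfg)
  expect_equal(max(m), 100)
  surv <- vapply(1:50, function(s) {
    maps <- derive_model_maps(m, corruption_config(fn_rate = 0.3, seed = s))
    sum(!maps$provenance$erased)
  }, numeric(1))
  se <- sd(surv) / sqrt(length(surv))
  expect_lt(abs(mean(surv) - 70), 3 * se)
  # provenance agrees with the detection map for one seed
  maps <- derive_model_maps(m, corruption_config(fn_rate = 0.3, seed = 4))
  peaks <- EBImage::bwlabel((maps$det_map >= 0.99) * 1)
  expect_equal(max(peaks), sum(!maps$provenance$erased))
})

test_that("false positives surface in both maps", {
  m <- generate_instance_mask(synth_config(seed = 31))
  maps <- derive_model_maps(m, corruption_config(fp_count = 5, seed = 31))
  fp <- maps$provenance[is.na(maps$provenance$label), ]
  expect_equal(nrow(fp), 5)
  for (j in seq_len(nrow(fp))) {
    yx <- c(fp$center_y[j] + 1, fp$center_x[j] + 1)
    expect_gte(maps$prob_map[yx[1], yx[2]], 0.5)
    expect_gte(maps$det_map[yx[1], yx[2]], 0.99)
    expect_equal(m[yx[1], yx[2]], 0L)  # placed in true background
  }
})

test_that("generate_dataset writes a reproducible, recountable manifest", {
  d0 <- withr::local_tempdir()
  p0 <- generate_dataset(0, synth_config(seed = 1), dir = d0)
  expect_length(readLines(p0), 1)  # header only

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config(nucleus_count_range = c(5, 12), seed = 6)
  cor <- corruption_config(fn_rate = 0.2, seed = 6)
  p1 <- generate_dataset(8, cfg, cor, dir = d1)
  p2 <- generate_dataset(8, cfg, cor, dir = d2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical manifests
  expect_error(generate_dataset(8, cfg, cor, dir = d1), "overwrite")

  man <- read.csv(p1)
  recount <- vapply(man$mask, function(f) {
    max(read_label_mask(file.path(d1, f)))
  }, numeric(1))
  expect_equal(unname(recount), man$truth_count)
  expect_equal(sum(man$truth_count), sum(recount))
})
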