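# Synthetic lesion-image generator.

test_that("lesion masks hit the requested area fraction", {
  cfg <- synth_config(n_images = 1, side = 100, n_lesions = c(1L, 1L),
                      area_frac = c(0.25, 0.25), seed = 1)
  set.seed(61)
  for (i in 1:10) {
    lm <- make_lesion_mask(cfg)
    expect_true(abs(sum(lm$mask) - 2500) <= 500)
    expect_true(all(lm$mask %in% c(0L, 1L)))   # exactly binary
  }
})

test_that("mask generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_images = 1, side = 60, seed = 1)
  m1 <- local({ set.seed(7); make_lesion_mask(cfg) })
  m2 <- local({ set.seed(7); make_lesion_mask(cfg) })
  expect_identical(m1, m2)
})

test_that("infeasible area ranges are rejected", {
  expect_error(synth_config(side = 20, area_frac = c(0.001, 0.01)),
               class = "capseg_config_error")
  expect_error(synth_config(area_frac = c(0.1, 0.6)),
               class = "capseg_config_error")
})

test_that("generated datasets are byte-identical under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synth_config(n_images = 10, side = 49, seed = 13)
  i1 <- generate_dataset(cfg, d1)
  i2 <- generate_dataset(cfg, d2)
  expect_identical(i1$split, i2$split)
  for (k in seq_len(nrow(i1))) {
    expect_identical(readBin(i1$image[k], "raw", 1e6),
                     readBin(i2$image[k], "raw", 1e6))
    expect_identical(readBin(i1$mask[k], "raw", 1e6),
                     readBin(i2$mask[k], "raw", 1e6))
  }
})

test_that("dataset generation writes n pairs with an 8:1:1 split", {
  d <- withr::local_tempdir()
  idx <- generate_dataset(synth_config(n_images = 40, side = 49, seed = 7), d)
  expect_equal(nrow(idx), 40L)
  expect_equal(as.integer(table(idx$split)[c("train", "val", "test")]),
               c(32L, 4L, 4L))
  expect_true(all(file.exists(idx$image)))
  expect_true(all(file.exists(idx$mask)))
  s <- load_pair(idx$image[1], idx$mask[1], 49)
  expect_true(all(s$mask %in% c(0L, 1L)))
})

test_that("zero contrast leaves foreground indistinguishable", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_images = 12, side = 64, contrast = 0, blur_sigma = 0,
                      texture_sd = 0, noise_sd = 10, seed = 21)
  idx <- generate_dataset(cfg, d)
  dfg <- dbg <- c()
  for (k in seq_len(nrow(idx))) {
    img <- capseg:::read_image_array(idx$image[k])[, , 1] * 255
    m <- capseg:::read_mask_array(idx$mask[k]) >= 128 / 255
    dfg <- c(dfg, img[m])
    dbg <- c(dbg, img[!m])
  }
  # two-sample mean difference within 2 sd / sqrt(n)
  se <- 2 * 10 * sqrt(1 / length(dfg) + 1 / length(dbg))
  expect_lt(abs(mean(dfg) - mean(dbg)), 2 + se)  # +2 for 8-bit quantisation
})

test_that("small-target preset keeps every mask under 1% foreground", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_images = 12, side = 97, preset = "small-target",
                      seed = 3)
  idx <- generate_dataset(cfg, d)
  for (k in seq_len(nrow(idx))) {
    m <- capseg:::read_mask_array(idx$mask[k]) >= 128 / 255
    expect_lt(mean(m), 0.01)
    expect_gt(sum(m), 0)
  }
})

test_that("easy preset is separable by a midpoint threshold", {
  idx <- tiny_dataset(side = 97, n = 12, seed = 17)
  cfg <- synth_config(side = 97, preset = "easy")
  cc <- NULL
  for (k in seq_len(nrow(idx))) {
    img <- capseg:::read_image_array(idx$image[k])[, , 1] * 255
    gt <- matrix(as.integer(
      capseg:::read_mask_array(idx$mask[k]) >= 128 / 255), 97, 97)
    pred <- matrix(as.integer(img > cfg$base + cfg$contrast / 2), 97, 97)
    ci <- confusion_counts(pred, gt)
    cc <- if (is.null(cc)) ci else cc + ci
  }
  m <- compute_metrics(cc)
  expect_gte(m$fg_iou, 90)   # sanity floor any trained model must beat
})
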