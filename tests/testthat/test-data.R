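# Loading, preprocessing, augmentation and splitting.

write_pair <- function(dir, stem, side = 24, mask_vals = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  img <- array(runif(side * side * 3), c(side, side, 3))
  if (is.null(mask_vals)) mask_vals <- matrix(sample(0:1, side^2, TRUE), side)
  png::writePNG(img, file.path(dir, "images", paste0(stem, ".png")))
  write_mask_png(mask_vals, file.path(dir, "masks", paste0(stem, ".png")))
  list(image = file.path(dir, "images", paste0(stem, ".png")),
       mask = file.path(dir, "masks", paste0(stem, ".png")),
       mask_vals = mask_vals)
}

test_that("pairs are resized, normalized and label-remapped", {
  d <- withr::local_tempdir()
  p <- write_pair(d, "a", side = 64)
  s <- load_pair(p$image, p$mask, side = 47)
  expect_s3_class(s, "seg_sample")
  expect_equal(dim(s$image), c(3L, 47L, 47L))
  expect_equal(dim(s$mask), c(47L, 47L))
  expect_true(all(s$mask %in% c(0L, 1L)))   # nearest neighbour never blends
  expect_true(all(s$image >= -1 - 1e-9 & s$image <= 1 + 1e-9))

  # no resize when sizes already match: values survive the round trip
  s2 <- load_pair(p$image, p$mask, side = 64)
  expect_identical(s2$mask, p$mask_vals)

  all255 <- write_pair(d, "b", side = 20, mask_vals = matrix(1L, 20, 20))
  s3 <- load_pair(all255$image, all255$mask, side = 20)
  expect_true(all(s3$mask == 1L))
})

test_that("mismatched or unreadable pairs raise typed errors", {
  d <- withr::local_tempdir()
  p1 <- write_pair(d, "a", side = 24)
  p2 <- write_pair(d, "b", side = 30)
  expect_error(load_pair(p1$image, p2$mask, 24),
               class = "capseg_invalid_input")
  expect_error(load_pair(file.path(d, "nope.png"), p1$mask, 24),
               class = "capseg_io_error")
})

test_that("masks round-trip through PNG exactly", {
  d <- withr::local_tempdir()
  m <- matrix(sample(0:1, 33 * 33, TRUE), 33, 33)
  f <- file.path(d, "m.png")
  write_mask_png(m, f)
  back <- capseg:::read_mask_array(f)
  expect_identical(matrix(as.integer(back >= 128 / 255), 33, 33), m)
})

test_that("augmentation is identity-preserving and involutive", {
  d <- withr::local_tempdir()
  p <- write_pair(d, "a", side = 32)
  s <- load_pair(p$image, p$mask, 32)
  # draws forced: no flips, angle 0 -> unchanged
  id <- local({
    set.seed(1)  # seed irrelevant: p_flip 0, angle 0
    augment_sample(s, max_angle = 0, p_flip = 0)
  })
  expect_identical(id$mask, s$mask)
  expect_equal(id$image, s$image)
  # two horizontal flips restore the original exactly
  flip_once <- function(x) {
    x$image <- x$image[, , rev(seq_len(dim(x$image)[3])), drop = FALSE]
    x$mask <- x$mask[, rev(seq_len(ncol(x$mask))), drop = FALSE]
    x
  }
  expect_identical(flip_once(flip_once(s))$mask, s$mask)
})

test_that("rotation roughly preserves the area of a centred disk", {
  S <- 64
  idx <- expand.grid(r = 1:S, c = 1:S)
  disk <- matrix(as.integer((idx$r - 32.5)^2 + (idx$c - 32.5)^2 <= 12^2),
                 S, S)
  img <- array(rnorm(3 * S * S), c(3, S, S))
  n0 <- sum(disk)
  set.seed(55)
  for (i in 1:100) {
    a <- augment_sample(structure(list(image = img, mask = disk),
                                  class = "seg_sample"),
                        max_angle = 30, p_flip = 0.5)
    expect_lt(abs(sum(a$mask) - n0) / n0, 0.15)
  }
})

test_that("splits use largest-remainder rounding and are reproducible", {
  idx <- split_dataset(sprintf("s%04d", 1:1008), seed = 3)
  expect_equal(as.integer(table(idx$split)[c("train", "val", "test")]),
               c(806L, 101L, 101L))
  small <- split_dataset(sprintf("s%02d", 1:10), seed = 3)
  expect_equal(as.integer(table(small$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  again <- split_dataset(sprintf("s%04d", 1:1008), seed = 3)
  expect_identical(idx$split, again$split)
  other <- split_dataset(sprintf("s%04d", 1:1008), seed = 4)
  expect_false(identical(idx$split, other$split))
  expect_error(split_dataset(letters[1:5]), class = "capseg_config_error")
})

test_that("splits partition the records", {
  idx <- split_dataset(sprintf("s%03d", 1:123), seed = 9)
  expect_equal(sort(unique(idx$split)), c("test", "train", "val"))
  expect_equal(nrow(idx), 123L)
  expect_false(any(duplicated(idx$stem)))
})

test_that("the index survives a TSV round trip", {
  d <- withr::local_tempdir()
  for (s in sprintf("s%02d", 1:12)) write_pair(d, s, side = 16)
  idx <- build_index(d, seed = 2)
  f <- file.path(d, "index.tsv")
  write_index(idx, f)
  back <- read_index(f)
  expect_equal(back$stem, idx$stem)
  expect_equal(back$split, idx$split)
})
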