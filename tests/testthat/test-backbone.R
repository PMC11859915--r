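# MobileNetV2-style dilated feature extractor.

test_that("deep feature geometry follows floor((S-1)/stride)+1", {
  bb <- make_backbone(backbone_config(), seed = 1)
  x <- array(rnorm(3 * 97 * 97), c(3, 97, 97))
  out <- backbone_forward(x, bb)
  expect_equal(dim(out$deep), c(320L, 13L, 13L, 1L))   # (97-1)/8+1
  expect_equal(dim(out$stem), c(32L, 49L, 49L, 1L))    # stride-2 stem
  # the formula the shapes must satisfy, at the reference sizes
  side_of <- function(S, os) floor((S - 1) / os) + 1
  expect_equal(side_of(473, 8), 60)
  expect_equal(side_of(97, 8), 13)
})

test_that("non-3-channel input is rejected", {
  bb <- make_backbone(backbone_config(), seed = 1)
  expect_error(backbone_forward(array(1, c(1, 41, 41)), bb),
               class = "capseg_invalid_input")
  expect_error(backbone_forward(array(1, c(3, 20, 20)), bb),
               class = "capseg_invalid_input")
})

test_that("truncated extractor parameter count matches layer arithmetic", {
  bb <- make_backbone(backbone_config(), seed = 1, ca_enabled = FALSE)
  expect_equal(capseg:::count_params_list(bb$params), oracle_backbone_count())
  expect_equal(oracle_backbone_count(), 1811712)
})

test_that("construction is seeded and monotone in width", {
  b1 <- make_backbone(backbone_config(), seed = 4)
  b2 <- make_backbone(backbone_config(), seed = 4)
  expect_identical(b1$params, b2$params)
  b3 <- make_backbone(backbone_config(), seed = 5)
  expect_false(identical(b1$params[["backbone.stem.conv.w"]],
                         b3$params[["backbone.stem.conv.w"]]))
  # dilation carries no parameters
  c8 <- make_backbone(backbone_config(output_stride = 8), seed = 1,
                      ca_enabled = FALSE)
  c16 <- make_backbone(backbone_config(output_stride = 16), seed = 1,
                       ca_enabled = FALSE)
  expect_equal(capseg:::count_params_list(c8$params),
               capseg:::count_params_list(c16$params))
  half <- make_backbone(backbone_config(width = 0.5), seed = 1,
                        ca_enabled = FALSE)
  expect_lt(capseg:::count_params_list(half$params),
            capseg:::count_params_list(c8$params))
  expect_error(backbone_config(output_stride = 4),
               class = "capseg_config_error")
})

test_that("stride-8 plan dilates the late stages instead of striding", {
  plan <- capseg:::backbone_plan(backbone_config(output_stride = 8))
  ch <- vapply(plan$blocks, function(b) b$cout, integer(1))
  dil <- vapply(plan$blocks, function(b) b$dil, integer(1))
  st <- vapply(plan$blocks, function(b) b$stride, integer(1))
  expect_true(all(dil[ch %in% c(64, 96)] == 2L))
  expect_true(all(dil[ch %in% c(160, 320)] == 4L))
  expect_true(all(st[ch %in% c(64, 160)] == 1L))
  # at stride 16 the 64-stage still downsamples
  p16 <- capseg:::backbone_plan(backbone_config(output_stride = 16))
  st16 <- vapply(p16$blocks, function(b) b$stride, integer(1))
  ch16 <- vapply(p16$blocks, function(b) b$cout, integer(1))
  expect_equal(st16[which(ch16 == 64)[1]], 2L)
})

test_that("deep features are translation covariant", {
  bb <- make_backbone(backbone_config(), seed = 2)
  S <- 97
  mk <- function(col) {
    x <- array(0, c(3, S, S))
    x[, 45:53, col:(col + 8)] <- 1
    x
  }
  d1 <- backbone_forward(mk(29), bb)$deep
  d2 <- backbone_forward(mk(37), bb)$deep   # shifted 8 px -> 1 cell
  r1 <- apply(abs(d1[, , , 1]), c(2, 3), sum)
  r2 <- apply(abs(d2[, , , 1]), c(2, 3), sum)
  # column shift maximising the cross-correlation of the responses
  shifts <- -3:3
  score <- vapply(shifts, function(s) {
    cols <- intersect(seq_len(13), seq_len(13) - s)
    sum(r1[, cols] * r2[, cols + s])
  }, numeric(1))
  best <- shifts[which.max(score)]
  expect_lte(abs(best - 1), 1)   # response moved by one cell (+/-1)
})

test_that("every backbone parameter receives gradient", {
  bb <- make_backbone(backbone_config(), seed = 3)
  set.seed(31)
  nz <- new.env()
  for (rep in 1:2) {
    x <- array(rnorm(3 * 41 * 41 * 2), c(3, 41, 41, 2))
    tape <- capseg:::new_tape(bb$params, bb$buffers, training = TRUE)
    out <- capseg:::forward_backbone(tape, capseg:::op_input(tape, x),
                                     bb$plan, bb$ca)
    gout <- array(rnorm(length(out$deep$val)), dim(out$deep$val))
    capseg:::tp_backward(tape, out$deep, gout)
    for (nm in names(bb$params)) {
      g <- tape$grads[[nm]]
      if (!is.null(g) && any(g != 0)) nz[[nm]] <- TRUE
    }
  }
  missing <- setdiff(names(bb$params), ls(nz))
  expect_length(missing, 0)
})
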