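# Training loop, evaluation harness, checkpointing, lambda sweep.

small_cfg <- function(epochs = 1L, seed = 1L, lambda = 0.6) {
  train_config(epochs = epochs, batch_size = 8L, seed = seed,
               net = network_config(input_side = 41L),
               loss = loss_config(lambda = lambda))
}

test_that("training is deterministic under a fixed seed", {
  idx <- tiny_dataset()
  r1 <- train_model(small_cfg(seed = 2L), idx)
  r2 <- train_model(small_cfg(seed = 2L), idx)
  expect_equal(r1$history$train_loss[1], r2$history$train_loss[1],
               tolerance = 1e-6)
  expect_identical(r1$history$val_miou, r2$history$val_miou)
  r3 <- train_model(small_cfg(seed = 3L), idx)
  expect_false(isTRUE(all.equal(r1$history$train_loss[1],
                                r3$history$train_loss[1])))
})

test_that("pure-dice and pure-focal runs complete without NaN", {
  d <- withr::local_tempdir()
  idx <- generate_dataset(
    synth_config(n_images = 20, side = 97, preset = "small-target",
                 seed = 19), d)
  for (lam in c(0, 1)) {
    cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 1L,
                        net = network_config(input_side = 97L),
                        loss = loss_config(lambda = lam))
    run <- train_model(cfg, idx)
    expect_true(all(is.finite(run$history$train_loss)))
  }
})

test_that("checkpoints round-trip the validation score exactly", {
  idx <- tiny_dataset()
  run <- memo("tiny_run", train_model(small_cfg(epochs = 2L), idx))
  f <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(run, f)
  back <- load_checkpoint(f)
  ev1 <- evaluate_model(run, idx, "val")
  ev2 <- evaluate_model(back, idx, "val")
  expect_identical(ev1$report$miou, ev2$report$miou)
  expect_identical(ev1$per_image$fg_iou, ev2$per_image$fg_iou)
})

test_that("an ideal predictor scores 100 on every metric", {
  idx <- tiny_dataset()
  ev <- evaluate_model(function(s) s$mask, idx, "val", side = 41L)
  expect_equal(ev$report$miou, 100)
  expect_equal(ev$report$mpa, 100)
  expect_equal(ev$report$precision, 100)
  expect_equal(ev$report$global_acc, 100)
})

test_that("all-background predictions expose the imbalance failure mode", {
  d <- withr::local_tempdir()
  idx <- generate_dataset(
    synth_config(n_images = 20, side = 97, preset = "small-target",
                 seed = 23), d)
  ev <- evaluate_model(function(s) matrix(0L, nrow(s$mask), ncol(s$mask)),
                       idx, "val", side = 97L)
  expect_gt(ev$report$global_acc, 99)
  expect_lt(ev$report$miou, 51)
})

test_that("evaluation writes the report CSV with the contracted columns", {
  idx <- tiny_dataset()
  run <- memo("tiny_run", train_model(small_cfg(epochs = 2L), idx))
  f <- file.path(withr::local_tempdir(), "report.csv")
  ev <- evaluate_model(run, idx, "val", out_csv = f)
  got <- utils::read.csv(f)
  expect_true(all(c("split", "n_images", "mIoU", "mPA", "Precision",
                    "Recall", "GlobalAcc") %in% names(got)))
  expect_equal(got$mIoU, round(ev$report$miou, 2))
  expect_equal(nrow(ev$per_image), sum(idx$split == "val"))
})

test_that("lambda sweep deduplicates, sorts, and writes a CSV", {
  idx <- tiny_dataset()
  f <- file.path(withr::local_tempdir(), "sweep.csv")
  tab <- lambda_sweep(small_cfg(), c(1, 0.5, 0.5, 0), idx, out_csv = f)
  expect_equal(tab$lambda, c(0, 0.5, 1))
  expect_true(all(is.finite(tab$val_miou)))
  got <- utils::read.csv(f)
  expect_equal(got$lambda, c(0, 0.5, 1))
  expect_false(is.unsorted(got$lambda))
  expect_error(lambda_sweep(small_cfg(), c(-0.1, 0.5), idx),
               class = "capseg_config_error")
})

test_that("configs survive a YAML round trip", {
  d <- withr::local_tempdir()
  cfg <- train_config(epochs = 12L, seed = 5L,
                      net = network_config(input_side = 97L,
                                           ca_reduction = 8L),
                      loss = loss_config(lambda = 0.3))
  f <- file.path(d, "cfg.yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$epochs, 12L)
  expect_equal(back$net$ca_reduction, 8L)
  expect_equal(back$loss$lambda, 0.3)
  expect_equal(back$net$input_side, 97L)
})

test_that("empty splits are a configuration error", {
  idx <- tiny_dataset()
  idx2 <- idx[idx$split != "val", ]
  expect_error(train_model(small_cfg(), idx2),
               class = "capseg_config_error")
  expect_error(evaluate_model(function(s) s$mask, idx2, "val"),
               class = "capseg_config_error")
})
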