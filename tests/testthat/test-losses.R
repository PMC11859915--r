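# Dice, Focal and the lambda-weighted mixture.

test_that("dice loss reproduces direct arithmetic", {
  G <- c(1, 1, 0, 0)
  P <- c(0.8, 0.6, 0.2, 0.1)
  # sum(GP)=1.4, sum(G)=2, sum(P)=1.7 -> 1 - 2.8/3.7
  expect_equal(dice_loss(P, G, eps = 0), 1 - 2.8 / 3.7, tolerance = 1e-10)

  # perfect hard overlap
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(dice_loss(m, m, eps = 0), 0)

  # empty-mask convention: eps/eps -> loss 0
  z <- matrix(0, 3, 3)
  expect_equal(dice_loss(z, z, eps = 1e-5), 0)
})

test_that("focal loss reproduces direct arithmetic and degeneracies", {
  expect_equal(focal_loss(matrix(1), matrix(1L)), 0)
  # single pixel p_t = 0.5: 0.25 * 0.25 * log 2
  expect_equal(focal_loss(matrix(0.5), matrix(1L)),
               0.25 * 0.25 * log(2), tolerance = 1e-6)
  expect_equal(0.25 * 0.25 * log(2), 0.04332, tolerance = 1e-4)

  # gamma = 0, alpha = 1 reduces to mean cross-entropy
  set.seed(3)
  G <- matrix(sample(0:1, 25, TRUE), 5, 5)
  P <- matrix(runif(25, 0.05, 0.95), 5, 5)
  pt <- ifelse(G == 1, P, 1 - P)
  expect_equal(focal_loss(P, G, alpha = 1, gamma = 0), mean(-log(pt)),
               tolerance = 1e-6)
})

test_that("focal loss accepts K-class probability arrays", {
  set.seed(4)
  G <- matrix(sample(0:1, 16, TRUE), 4, 4)
  Pfg <- matrix(runif(16, 0.1, 0.9), 4, 4)
  Pk <- array(0, c(2, 4, 4))
  Pk[1, , ] <- 1 - Pfg
  Pk[2, , ] <- Pfg
  expect_equal(focal_loss(Pk, G), focal_loss(Pfg, G), tolerance = 1e-12)
  expect_equal(dice_loss(Pk, G), dice_loss(Pfg, G), tolerance = 1e-12)
  expect_error(focal_loss(array(0.5, c(2, 3, 3)), G),
               class = "capseg_invalid_input")
})

test_that("mixed loss interpolates its endpoints affinely", {
  G <- c(1, 1, 0, 0)
  P <- c(0.8, 0.6, 0.2, 0.1)
  d <- dice_loss(P, G, eps = 0)
  f <- focal_loss(P, G)
  cfg0 <- loss_config(lambda = 0, eps = 0)
  cfg1 <- loss_config(lambda = 1, eps = 0)
  cfg6 <- loss_config(lambda = 0.6, eps = 0)
  expect_equal(mixed_loss(P, G, cfg1), d)
  expect_equal(mixed_loss(P, G, cfg0), f)
  expect_equal(mixed_loss(P, G, cfg6), 0.6 * d + 0.4 * f)
  # worked mixture: dice of the 4-pixel example with the 1-pixel focal value
  expect_lt(abs(0.6 * d + 0.4 * focal_loss(matrix(0.5), matrix(1L)) -
                  0.16325), 1e-4)
  # affinity in lambda
  cfg5 <- loss_config(lambda = 0.5, eps = 0)
  expect_equal(mixed_loss(P, G, cfg5),
               (mixed_loss(P, G, cfg0) + mixed_loss(P, G, cfg1)) / 2,
               tolerance = 1e-9)
})

test_that("loss configuration is validated", {
  expect_error(loss_config(lambda = 1.2), class = "capseg_config_error")
  expect_error(loss_config(gamma = -1), class = "capseg_config_error")
})

test_that("losses stay within their ranges on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    G <- matrix(sample(0:1, 36, TRUE, prob = c(0.8, 0.2)), 6, 6)
    P <- matrix(runif(36), 6, 6)
    d <- dice_loss(P, G)
    f <- focal_loss(P, G)
    expect_true(d >= 0 && d <= 1 + 1e-9)
    expect_gte(f, 0)
    expect_gte(mixed_loss(P, G), 0)
  }
})

test_that("analytic mixed-loss gradient matches finite differences", {
  set.seed(12)
  logits <- array(rnorm(2 * 4 * 4 * 1), c(2, 4, 4, 1))
  gt <- array(sample(0:1, 16, TRUE), c(4, 4, 1))
  cfg <- loss_config()
  lg <- capseg:::mixed_loss_grad(logits, gt, cfg)
  f <- function(z) {
    P <- capseg:::softmax_ch(array(z, dim(logits)))
    mixed_loss(P, gt, cfg)
  }
  expect_equal(lg$loss, f(logits), tolerance = 1e-10)
  fd <- fd_gradient(f, logits)
  denom <- pmax(abs(fd), 1e-5)
  expect_lt(max(abs(lg$grad - fd) / denom), 1e-3)

  # per-image dice mode gradient as well
  logits2 <- array(rnorm(2 * 3 * 3 * 2), c(2, 3, 3, 2))
  gt2 <- array(sample(0:1, 18, TRUE), c(3, 3, 2))
  cfg2 <- loss_config(dice_mode = "image")
  lg2 <- capseg:::mixed_loss_grad(logits2, gt2, cfg2)
  f2 <- function(z) {
    P <- capseg:::softmax_ch(array(z, dim(logits2)))
    mixed_loss(P, gt2, cfg2)
  }
  fd2 <- fd_gradient(f2, logits2)
  expect_lt(max(abs(lg2$grad - fd2) / pmax(abs(fd2), 1e-5)), 1e-3)
})

test_that("dice stays informative where pixel accuracy saturates", {
  # 100x100 mask with a 3x3 lesion: the all-background predictor is
  # 99.91% accurate, yet a non-committal P = 0.5 has dice loss > 0.9
  G <- matrix(0L, 100, 100)
  G[49:51, 49:51] <- 1L
  P <- matrix(0.5, 100, 100)
  expect_gt(dice_loss(P, G), 0.9)
  acc <- mean((G == 0))
  expect_gt(acc, 0.999)
})
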