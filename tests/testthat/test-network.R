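# Assembled network: pyramid pooling head, classifier, parameter budget.

test_that("default parameter budget sits at the published 2.39 M", {
  net <- memo("net_default", make_network(network_config(), seed = 1))
  total <- count_parameters(net)
  expect_lt(abs(total / 1e6 - 2.39), 0.05)
})

test_that("module counts are additive and ablate exactly", {
  net <- memo("net_default", make_network(network_config(), seed = 1))
  br <- parameter_breakdown(net)
  expect_identical(unname(br[["total"]]), unname(sum(br[names(br) != "total"])))
  expect_identical(br[["total"]], count_parameters(net))
  # disabling both CA blocks removes exactly their own parameters
  noca <- make_network(network_config(ca_enabled = FALSE), seed = 1)
  expect_equal(count_parameters(net) - count_parameters(noca),
               ca_param_count(attention_config(32, 16)) +
                 ca_param_count(attention_config(320, 16)))
  # one extra class costs head_channels + 1 classifier scalars
  k3 <- make_network(network_config(num_classes = 3), seed = 1)
  expect_equal(count_parameters(k3) - count_parameters(net), 81L)
})

test_that("pyramid head fuses 640 channels at the defaults", {
  cfg <- network_config(input_side = 97)
  expect_equal(cfg$branch_channels, 80L)
  expect_equal(320L + length(cfg$bins) * cfg$branch_channels, 640L)
  net <- memo("net97", make_network(cfg, seed = 1))
  deep <- array(rnorm(320 * 13 * 13), c(320, 13, 13))
  h <- ppm_forward(deep, net)
  expect_equal(dim(h), c(80L, 13L, 13L))
})

test_that("adaptive pooling of a constant map stays constant", {
  x <- array(3.25, c(5, 13, 13, 1))
  for (b in c(1L, 2L, 3L, 6L)) {
    p <- capseg:::cpp_adapt_pool_fwd(x, dim(x), b, b)
    expect_equal(as.vector(p), rep(3.25, 5 * b * b))
  }
  # bin == spatial side: identity-resolution pooling returns the map itself
  p <- capseg:::cpp_adapt_pool_fwd(x, dim(x), 13L, 13L)
  expect_equal(p, x, ignore_attr = TRUE)
})

test_that("bins larger than the deep map are a configuration error", {
  net <- make_network(network_config(input_side = 97, bins = c(1L, 14L)),
                      seed = 1)
  deep <- array(rnorm(320 * 13 * 13), c(320, 13, 13))
  expect_error(ppm_forward(deep, net), class = "capseg_config_error")
})

test_that("segmentation output is a normalized probability map", {
  net <- memo("net97", make_network(network_config(input_side = 97), seed = 1))
  set.seed(41)
  x <- array(rnorm(3 * 97 * 97 * 2), c(3, 97, 97, 2))
  out <- segment_forward(x, net)
  expect_equal(dim(out$logits), c(2L, 97L, 97L, 2L))
  sums <- apply(out$probs, c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(out$probs >= 0))
})

test_that("samples are independent and eval passes deterministic", {
  net <- memo("net97", make_network(network_config(input_side = 97), seed = 1))
  set.seed(42)
  x <- array(rnorm(3 * 97 * 97 * 3), c(3, 97, 97, 3))
  o1 <- segment_forward(x, net)
  o2 <- segment_forward(x, net)
  expect_identical(o1$logits, o2$logits)  # bitwise determinism
  perm <- c(3, 1, 2)
  op <- segment_forward(x[, , , perm], net)
  expect_equal(op$logits, o1$logits[, , , perm], tolerance = 1e-12)
})

test_that("compiled executor agrees with the reference tape", {
  net <- memo("net97", make_network(network_config(input_side = 97), seed = 1))
  set.seed(43)
  x <- array(rnorm(3 * 97 * 97 * 2), c(3, 97, 97, 2))
  ref <- segment_forward(x, net)$logits
  fast <- capseg:::vm_forward_logits(net, x, training = FALSE)
  expect_equal(as.vector(fast), as.vector(ref), tolerance = 1e-4)
})

test_that("network configuration is validated", {
  expect_error(network_config(bins = c(2, 1)), class = "capseg_config_error")
  expect_error(network_config(num_classes = 1), class = "capseg_config_error")
})
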