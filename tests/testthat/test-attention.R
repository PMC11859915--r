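# Coordinate-attention block: directional pooling, gate generation,
# reweighting, and parameter accounting.

test_that("directional pooling returns row and column means", {
  # 1x2x2 map [[1,2],[3,4]]: row means 1.5/3.5, column means 2/3
  x <- array(c(1, 3, 2, 4), c(1, 2, 2))
  p <- directional_pool(x)
  expect_equal(as.vector(p$zh), c(1.5, 3.5))
  expect_equal(as.vector(p$zw), c(2, 3))
  expect_equal(dim(p$zh), c(1L, 2L, 1L))
  expect_equal(dim(p$zw), c(1L, 1L, 2L))

  xk <- array(7.5, c(3, 4, 5))
  pk <- directional_pool(xk)
  expect_true(all(pk$zh == 7.5) && all(pk$zw == 7.5))

  set.seed(1)
  xr <- array(rnorm(4 * 7 * 5), c(4, 7, 5))
  pr <- directional_pool(xr)
  orc <- oracle_directional_pool(xr)
  expect_equal(pr$zh, orc$zh, tolerance = 1e-6)
  expect_equal(pr$zw, orc$zw, tolerance = 1e-6)
})

test_that("pooling matches the loop oracle on many random shapes", {
  set.seed(42)
  for (i in 1:100) {
    d <- sample(2:6, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    p <- directional_pool(x)
    orc <- oracle_directional_pool(x)
    expect_lt(max(abs(p$zh - orc$zh), abs(p$zw - orc$zw)), 1e-6)
  }
})

test_that("pooling rejects degenerate input", {
  expect_error(directional_pool(array(1, c(2, 0, 3))),
               class = "capseg_invalid_input")
  expect_error(directional_pool(array(c(1, NA), c(2, 1, 1))),
               class = "capseg_invalid_input")
})

test_that("hidden width uses the floor-at-8 reduction rule", {
  expect_equal(attention_config(32, 16)$hidden, 8L)   # 32/16 = 2 -> floor 8
  expect_equal(attention_config(8, 8)$hidden, 8L)
  expect_equal(attention_config(320, 16)$hidden, 20L)
})

test_that("zeroed restoring convolutions give gates of exactly 0.5", {
  cfg <- attention_config(4, 2)
  params <- ca_init_params(cfg, seed = 1)
  for (nm in c("ca.fh.w", "ca.fh.b", "ca.fw.w", "ca.fw.b"))
    params[[nm]][] <- 0
  p <- directional_pool(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  g <- attention_maps(p, cfg, params)
  expect_true(all(g$gh == 0.5) && all(g$gw == 0.5))
})

test_that("gate maps have the contracted shapes", {
  cfg <- attention_config(32, 16)
  params <- ca_init_params(cfg, seed = 2)
  x <- array(rnorm(32 * 60 * 60), c(32, 60, 60))
  g <- attention_maps(directional_pool(x), cfg, params)
  expect_equal(dim(g$gh), c(32L, 60L, 1L))
  expect_equal(dim(g$gw), c(32L, 1L, 60L))
  expect_true(all(g$gh > 0 & g$gh < 1))
  expect_true(all(g$gw > 0 & g$gw < 1))
})

test_that("gate generation matches a scalar loop oracle", {
  cfg <- attention_config(2, 1)  # hidden floors to 8
  params <- ca_init_params(cfg, seed = 3)
  x <- array(rnorm(2 * 3 * 3, sd = 0.5), c(2, 3, 3))
  p <- directional_pool(x)
  g <- attention_maps(p, cfg, params)
  orc <- oracle_attention_maps(p, cfg, params)
  expect_equal(g$gh, orc$gh, tolerance = 1e-6)
  expect_equal(g$gw, orc$gw, tolerance = 1e-6)
})

test_that("channel mismatch raises a configuration error", {
  cfg <- attention_config(4, 2)
  params <- ca_init_params(cfg, seed = 1)
  p <- directional_pool(array(rnorm(3 * 4 * 4), c(3, 4, 4)))
  expect_error(attention_maps(p, cfg, params),
               class = "capseg_config_error")
  expect_error(apply_coordinate_attention(array(1, c(5, 4, 4)), cfg, params),
               class = "capseg_config_error")
})

test_that("reweighting has identity, annihilation and boundedness limits", {
  cfg <- attention_config(3, 1)
  set.seed(7)
  x <- array(rnorm(3 * 6 * 4), c(3, 6, 4))

  params <- ca_init_params(cfg, seed = 1)
  for (nm in c("ca.fh.w", "ca.fw.w")) params[[nm]][] <- 0
  params[["ca.fh.b"]][] <- 10   # sigmoid(10) ~ 1
  params[["ca.fw.b"]][] <- 10
  expect_equal(apply_coordinate_attention(x, cfg, params), x,
               tolerance = 1e-3)

  params[["ca.fh.b"]][] <- -40  # sigmoid(-40) ~ 0
  params[["ca.fw.b"]][] <- -40
  expect_lt(max(abs(apply_coordinate_attention(x, cfg, params))), 1e-12)

  for (i in 1:100) {
    prand <- ca_init_params(cfg, seed = 100 + i)
    xr <- array(rnorm(3 * 4 * 5, sd = 2), c(3, 4, 5))
    y <- apply_coordinate_attention(xr, cfg, prand)
    expect_true(all(abs(y) <= abs(xr) + 1e-12))
  }
})

test_that("analytic attention gradients match finite differences", {
  cfg <- attention_config(2, 1)
  params <- ca_init_params(cfg, seed = 9)
  set.seed(10)
  x <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  proj <- array(rnorm(2 * 4 * 4), c(2, 4, 4, 1))

  run <- function(xv) {
    pn <- grep("running_", names(params), value = TRUE)
    tape <- capseg:::new_tape(params[setdiff(names(params), pn)],
                              capseg:::params_to_env(params[pn]))
    out <- capseg:::forward_ca(tape, capseg:::op_input(
      tape, array(xv, c(2, 4, 4, 1))), "ca", cfg)
    list(tape = tape, out = out$out)
  }
  f <- function(xv) sum(run(xv)$out$val * proj)
  # analytic gradient via a fresh tape that records the input node
  pn <- grep("running_", names(params), value = TRUE)
  tape <- capseg:::new_tape(params[setdiff(names(params), pn)],
                            capseg:::params_to_env(params[pn]))
  xin <- capseg:::op_input(tape, array(x, c(2, 4, 4, 1)))
  out <- capseg:::forward_ca(tape, xin, "ca", cfg)$out
  gtab_grad <- local({
    gtab <- vector("list", tape$n)
    gtab[[out$id]] <- proj
    for (id in seq(tape$n, 1L)) {
      node <- tape$nodes[[id]]
      g <- gtab[[id]]
      if (is.null(g) || is.null(node$backward)) next
      gs <- node$backward(g)
      for (k in seq_along(node$inputs)) {
        i <- node$inputs[k]
        if (is.null(gs[[k]])) next
        gtab[[i]] <- if (is.null(gtab[[i]])) gs[[k]] else gtab[[i]] + gs[[k]]
      }
    }
    gtab[[xin$id]]
  })
  fd <- fd_gradient(f, x)
  denom <- pmax(abs(fd), 1e-4)
  expect_lt(max(abs(array(gtab_grad, dim(x)) - fd) / denom), 1e-3)
})

test_that("parameter count follows the layer arithmetic", {
  # C=32, r=16, hidden 8: squeeze 32*8+8, norm 16, restores 2*(8*32+32)
  expect_equal(ca_param_count(attention_config(32, 16)),
               (32 * 8 + 8) + 16 + 2 * (8 * 32 + 32))
  expect_equal(ca_param_count(attention_config(32, 16)), 856L)
  # C=8, r=8, hidden max(8,1)=8: 72 + 16 + 144
  expect_equal(ca_param_count(attention_config(8, 8)), 232L)
  # counted parameters of an instantiated block agree with the formula
  cfg <- attention_config(24, 4)
  params <- ca_init_params(cfg, seed = 1)
  learnable <- params[!grepl("running_", names(params))]
  expect_equal(sum(lengths(learnable)), ca_param_count(cfg))
  # monotone in width above the floor
  expect_gt(ca_param_count(attention_config(64, 4)),
            ca_param_count(attention_config(32, 4)))
})
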