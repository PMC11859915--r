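#' Coordinate-attention configuration
#'
#' The coordinate-attention (CA) block factorises global pooling into two
#' directional strip pools (one along height, one along width), squeezes the
#' concatenated strips through a shared 1x1 bottleneck of width
#' `max(8, channels %/% reduction)`, and produces per-row and per-column
#' sigmoid gates that reweight the input feature map while preserving
#' positional information.
#'
#' @param channels Number of input/output channels C of the block.
#' @param reduction Bottleneck reduction factor r (default 16). The hidden
#'   width is floored at 8 so that small-C blocks keep a usable bottleneck.
#' @param activation Mid-block activation: `"hswish"` (hard-swish, default)
#'   or `"relu"`.
#' @return A list with class `attention_config`: `channels`, `reduction`,
#'   `hidden`, `activation`.
#' @export
attention_config <- function(channels, reduction = 16L,
                             activation = c("hswish", "relu")) {
  activation <- match.arg(activation)
  if (channels < 1 || reduction < 1)
    stop_config("channels and reduction must be positive")
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 hidden = max(8L, as.integer(channels) %/% as.integer(reduction)),
                 activation = activation),
            class = "attention_config")
}

# Append CA parameters for one block under `prefix` to a builder.
build_ca_params <- function(b, prefix, cfg) {
  C <- cfg$channels
  hid <- cfg$hidden
  add_conv(b, paste0(prefix, ".squeeze"), hid, C, bias = TRUE)
  add_bn(b, paste0(prefix, ".norm"), hid)
  add_conv(b, paste0(prefix, ".fh"), C, hid, bias = TRUE)
  add_conv(b, paste0(prefix, ".fw"), C, hid, bias = TRUE)
  invisible(b)
}

#' Initialise parameters for a standalone coordinate-attention block
#'
#' @param cfg An [attention_config()].
#' @param seed Integer seed for reproducible initialisation.
#' @return Named list of parameter arrays plus batch-norm running statistics,
#'   suitable for [attention_maps()] and [apply_coordinate_attention()].
#' @export
ca_init_params <- function(cfg, seed = 1L) {
  local_seed(seed, {
    b <- new_builder()
    build_ca_params(b, "ca", cfg)
    c(b$params, b$buffers)
  })
}

#' Directional strip pooling
#'
#' Decomposes global average pooling into two 1-D pools: `zh[c, h]` is the
#' mean of row h of channel c (pooling kernel (1, W)) and `zw[c, w]` is the
#' mean of column w (pooling kernel (H, 1)).
#'
#' @param x Feature map, numeric array `c(C, H, W)`.
#' @return List with `zh` (`c(C, H, 1)`) and `zw` (`c(C, 1, W)`).
#' @export
directional_pool <- function(x) {
  x <- as_chwn(x, "feature map")
  d <- dim(x)
  zh <- cpp_mean_w(x, d)
  zw <- cpp_mean_h(x, d)
  list(zh = array(zh, c(d[1], d[2], 1L)),
       zw = array(aperm(array(zw, c(d[1], d[3])), c(1, 2)),
                  c(d[1], 1L, d[3])))
}

# Tape forward of one CA block; x is a tape tensor c(C,H,W,N).
forward_ca <- function(tape, x, prefix, cfg) {
  d <- dim(x$val)
  H <- d[2]; W <- d[3]
  zh <- op_mean_w(tape, x)                    # c(C,H,1,N)
  zw <- op_mean_h(tape, x)                    # c(C,W,1,N)
  f <- op_concat2(tape, zh, zw)               # c(C,H+W,1,N)
  f <- op_conv(tape, f, paste0(prefix, ".squeeze"), bias = TRUE)
  f <- op_bn(tape, f, paste0(prefix, ".norm"))
  f <- op_act(tape, f, cfg$activation)
  fh <- op_slice2(tape, f, 1L, H)
  fw <- op_slice2(tape, f, H + 1L, H + W)
  gh <- op_act(tape, op_conv(tape, fh, paste0(prefix, ".fh"), bias = TRUE),
               "sigmoid")
  gw <- op_act(tape, op_conv(tape, fw, paste0(prefix, ".fw"), bias = TRUE),
               "sigmoid")
  list(out = op_scale_hw(tape, x, gh, gw), gh = gh, gw = gw)
}

ca_run <- function(x, cfg, params, want = c("out", "maps")) {
  want <- match.arg(want)
  x <- as_chwn(x, "feature map")
  if (dim(x)[1] != cfg$channels)
    stop_config("feature map has %d channels but config expects %d",
                dim(x)[1], cfg$channels)
  pn <- grep("running_", names(params), value = TRUE)
  tape <- new_tape(params[setdiff(names(params), pn)],
                   params_to_env(params[pn]), training = FALSE)
  res <- forward_ca(tape, op_input(tape, x), "ca", cfg)
  res
}

#' Coordinate-attention gate maps
#'
#' Runs the attention-generation half of the CA block: the pooled strips are
#' concatenated along the spatial axis, squeezed by a shared 1x1 convolution
#' with normalisation and a nonlinearity, split back into the height and
#' width parts, restored to C channels by two independent 1x1 convolutions,
#' and passed through sigmoids.
#'
#' @param p Output of [directional_pool()].
#' @param cfg An [attention_config()].
#' @param params Parameters from [ca_init_params()] (or trained values).
#' @return List with gate maps `gh` (`c(C, H, 1)`) and `gw` (`c(C, 1, W)`),
#'   every entry strictly in (0, 1).
#' @export
attention_maps <- function(p, cfg, params) {
  C <- dim(p$zh)[1]
  if (C != cfg$channels || dim(p$zw)[1] != cfg$channels)
    stop_config("pooled strips have %d channels but config expects %d",
                C, cfg$channels)
  H <- dim(p$zh)[2]
  W <- dim(p$zw)[3]
  # Rebuild a rank-1-in-W feature map whose strip pools equal p exactly is
  # not possible in general, so run the generation half directly.
  pn <- grep("running_", names(params), value = TRUE)
  tape <- new_tape(params[setdiff(names(params), pn)],
                   params_to_env(params[pn]), training = FALSE)
  zh <- op_input(tape, array(p$zh, c(C, H, 1L, 1L)))
  zw <- op_input(tape, array(p$zw, c(C, W, 1L, 1L)))
  f <- op_concat2(tape, zh, zw)
  f <- op_conv(tape, f, "ca.squeeze", bias = TRUE)
  f <- op_bn(tape, f, "ca.norm")
  f <- op_act(tape, f, cfg$activation)
  fh <- op_slice2(tape, f, 1L, H)
  fw <- op_slice2(tape, f, H + 1L, H + W)
  gh <- op_act(tape, op_conv(tape, fh, "ca.fh", bias = TRUE), "sigmoid")
  gw <- op_act(tape, op_conv(tape, fw, "ca.fw", bias = TRUE), "sigmoid")
  list(gh = array(gh$val, c(C, H, 1L)),
       gw = array(gw$val, c(C, 1L, W)))
}

#' Apply a coordinate-attention block to a feature map
#'
#' Full block: directional pooling, attention generation, and the
#' reweighting `y[c, i, j] = x[c, i, j] * gh[c, i] * gw[c, j]`.
#'
#' @inheritParams attention_maps
#' @param x Feature map `c(C, H, W)`.
#' @return Reweighted feature map with the same shape as `x`.
#' @export
apply_coordinate_attention <- function(x, cfg, params) {
  single <- length(dim(x)) == 3L
  res <- ca_run(x, cfg, params, "out")
  y <- res$out$val
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Learnable-parameter count of one coordinate-attention block
#'
#' Counts the squeeze convolution (weights + bias), its normalisation
#' (scale + shift), and the two restoring convolutions (weights + biases).
#'
#' @param cfg An [attention_config()].
#' @return Integer number of learnable scalars.
#' @export
ca_param_count <- function(cfg) {
  C <- cfg$channels
  hid <- cfg$hidden
  squeeze <- C * hid + hid
  norm <- 2L * hid
  restore <- 2L * (hid * C + C)
  as.integer(squeeze + norm + restore)
}
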