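#' Backbone configuration
#'
#' MobileNetV2-style feature extractor: a stride-2 stem convolution followed
#' by the canonical inverted-residual schedule, truncated before the 1280-
#' channel head (segmentation use). With `output_stride = 8` the stride-2
#' entries of the 64- and 160-channel stages are executed with stride 1 and
#' the depthwise convolutions of the affected stages are dilated (rates 2
#' and 4), so the deepest map keeps 1/8 resolution without extra parameters.
#'
#' @param width Width multiplier applied to all channel counts (default 1).
#' @param output_stride Ratio of input to deepest-feature resolution, 8 or 16.
#' @param schedule Inverted-residual schedule, a list of `c(t, c, n, s)`
#'   rows (expansion factor, output channels, repeats, first-block stride).
#' @return List with class `backbone_config`.
#' @export
backbone_config <- function(width = 1.0, output_stride = 8L,
                            schedule = NULL) {
  if (!output_stride %in% c(8L, 16L))
    stop_config("output_stride must be 8 or 16, got %s", output_stride)
  if (width <= 0) stop_config("width multiplier must be positive")
  if (is.null(schedule)) {
    schedule <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2),
                     c(6, 64, 4, 2), c(6, 96, 3, 1), c(6, 160, 3, 2),
                     c(6, 320, 1, 1))
  }
  structure(list(width = width, output_stride = as.integer(output_stride),
                 schedule = schedule),
            class = "backbone_config")
}

# Round channels to a multiple of 8, never dropping below 90% of the target
# (the MobileNetV2 width-scaling convention).
make_divisible <- function(v, divisor = 8L) {
  nv <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}

# Expand the schedule into per-block descriptors with dilation bookkeeping.
backbone_plan <- function(cfg) {
  wm <- cfg$width
  stem_ch <- make_divisible(32 * wm)
  blocks <- list()
  cin <- stem_ch
  current_stride <- 2L
  rate <- 1L
  bi <- 0L
  for (row in cfg$schedule) {
    t <- row[1]; ch <- row[2]; n <- row[3]; s <- row[4]
    cout <- make_divisible(ch * wm)
    for (k in seq_len(n)) {
      bi <- bi + 1L
      stride <- if (k == 1L) as.integer(s) else 1L
      dil <- rate
      if (stride == 2L) {
        if (current_stride >= cfg$output_stride) {
          rate <- rate * 2L
          dil <- rate   # converted stage is dilated throughout
          stride <- 1L
        } else {
          current_stride <- current_stride * 2L
        }
      }
      exp_ch <- if (t == 1) cin else as.integer(round(cin * t))
      blocks[[bi]] <- list(name = sprintf("backbone.block%02d", bi),
                           cin = cin, cout = cout, exp = exp_ch,
                           stride = stride, dil = as.integer(dil),
                           use_res = (stride == 1L && cin == cout))
      cin <- cout
    }
  }
  list(stem_ch = stem_ch, blocks = blocks, deep_ch = cin)
}

build_backbone_params <- function(b, cfg) {
  plan <- backbone_plan(cfg)
  add_conv(b, "backbone.stem.conv", plan$stem_ch, 3L, 3L, 3L)
  add_bn(b, "backbone.stem.bn", plan$stem_ch)
  for (blk in plan$blocks) {
    if (blk$exp != blk$cin) {
      add_conv(b, paste0(blk$name, ".expand"), blk$exp, blk$cin)
      add_bn(b, paste0(blk$name, ".expand_bn"), blk$exp)
    }
    add_conv(b, paste0(blk$name, ".dw"), blk$exp, blk$exp, 3L, 3L,
             groups = blk$exp)
    add_bn(b, paste0(blk$name, ".dw_bn"), blk$exp)
    add_conv(b, paste0(blk$name, ".project"), blk$cout, blk$exp)
    add_bn(b, paste0(blk$name, ".project_bn"), blk$cout)
  }
  plan
}

#' Construct a backbone feature extractor
#'
#' Deterministically initialises (He fan-in, seeded) the truncated
#' MobileNetV2-style extractor, optionally wrapped by coordinate-attention
#' blocks on the stem output and on the final deep map.
#'
#' @param cfg A [backbone_config()].
#' @param seed Integer seed for parameter initialisation.
#' @param ca_enabled Insert CA blocks before and after the inverted-residual
#'   stack (default TRUE).
#' @param ca_reduction,ca_activation Passed to [attention_config()].
#' @return List with class `capseg_backbone`: `cfg`, `plan`, `params`,
#'   `buffers`, `ca` (configs or NULL).
#' @export
make_backbone <- function(cfg = backbone_config(), seed = 1L,
                          ca_enabled = TRUE, ca_reduction = 16L,
                          ca_activation = "hswish") {
  local_seed(seed, {
    b <- new_builder()
    plan <- build_backbone_params(b, cfg)
    ca <- NULL
    if (ca_enabled) {
      ca <- list(ca1 = attention_config(plan$stem_ch, ca_reduction, ca_activation),
                 ca2 = attention_config(plan$deep_ch, ca_reduction, ca_activation))
      build_ca_params(b, "ca1", ca$ca1)
      build_ca_params(b, "ca2", ca$ca2)
    }
    structure(list(cfg = cfg, plan = plan, params = b$params,
                   buffers = params_to_env(b$buffers), ca = ca),
              class = "capseg_backbone")
  })
}

forward_invres <- function(tape, x, blk) {
  t <- x
  if (blk$exp != blk$cin) {
    t <- op_conv(tape, t, paste0(blk$name, ".expand"))
    t <- op_bn(tape, t, paste0(blk$name, ".expand_bn"))
    t <- op_act(tape, t, "relu6")
  }
  t <- op_dwconv(tape, t, paste0(blk$name, ".dw"), stride = blk$stride,
                 pad = blk$dil, dil = blk$dil)
  t <- op_bn(tape, t, paste0(blk$name, ".dw_bn"))
  t <- op_act(tape, t, "relu6")
  t <- op_conv(tape, t, paste0(blk$name, ".project"))
  t <- op_bn(tape, t, paste0(blk$name, ".project_bn"))
  if (blk$use_res) t <- op_add(tape, t, x)
  t
}

forward_backbone <- function(tape, x, plan, ca) {
  t <- op_conv(tape, x, "backbone.stem.conv", stride = 2L, pad = 1L)
  t <- op_bn(tape, t, "backbone.stem.bn")
  t <- op_act(tape, t, "relu6")
  if (!is.null(ca)) t <- forward_ca(tape, t, "ca1", ca$ca1)$out
  stem <- t
  for (blk in plan$blocks) t <- forward_invres(tape, t, blk)
  if (!is.null(ca)) t <- forward_ca(tape, t, "ca2", ca$ca2)$out
  list(stem = stem, deep = t)
}

#' Run the backbone on a batch of images
#'
#' @param images Numeric array `c(3, S, S)` or `c(3, S, S, N)`, S >= 33.
#' @param backbone A [make_backbone()] object.
#' @param training Use batch statistics and update running statistics.
#' @return List with `stem` (attention-weighted stem features, stride 2) and
#'   `deep` (attention-weighted deep features at the configured output
#'   stride), both `c(C, H, W, N)`.
#' @export
backbone_forward <- function(images, backbone, training = FALSE) {
  images <- as_chwn(images, "images")
  if (dim(images)[1] != 3L)
    stop_invalid("images must have 3 channels, got %d", dim(images)[1])
  if (dim(images)[2] < 33L || dim(images)[3] < 33L)
    stop_invalid("image side must be at least 33 pixels")
  tape <- new_tape(backbone$params, backbone$buffers, training = training)
  out <- forward_backbone(tape, op_input(tape, images), backbone$plan,
                          backbone$ca)
  list(stem = out$stem$val, deep = out$deep$val)
}
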