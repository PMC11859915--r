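#' Network configuration
#'
#' Assembles the full segmentation network: backbone with coordinate
#' attention, pyramid pooling head, 3x3 fusion convolution, dropout, and a
#' 1x1 classifier, with bilinear upsampling back to the input resolution.
#'
#' @param num_classes Number of output classes K (default 2: background and
#'   lesion).
#' @param input_side Default input side S in pixels (default 473).
#' @param bins Pyramid pooling grid sizes, ascending (default 1, 2, 3, 6).
#' @param branch_channels Channels of each pyramid branch; default
#'   `deep_channels / 4` (80 at width 1), so concatenation doubles width.
#' @param head_channels Channels after the 3x3 fusion convolution
#'   (default = `branch_channels`).
#' @param dropout Dropout rate before the classifier (default 0.1).
#' @param backbone A [backbone_config()].
#' @param ca_enabled,ca_reduction,ca_activation Coordinate-attention knobs.
#' @param align_corners Corner-aligned bilinear sampling (default TRUE;
#'   suits the odd "8k+1" input geometry such as 473 or 97).
#' @return List with class `network_config`.
#' @export
network_config <- function(num_classes = 2L, input_side = 473L,
                           bins = c(1L, 2L, 3L, 6L), branch_channels = NULL,
                           head_channels = NULL, dropout = 0.1,
                           backbone = backbone_config(),
                           ca_enabled = TRUE, ca_reduction = 16L,
                           ca_activation = "hswish",
                           align_corners = TRUE) {
  bins <- as.integer(bins)
  if (any(bins < 1L) || is.unsorted(bins, strictly = TRUE))
    stop_config("bins must be ascending integers >= 1")
  if (num_classes < 2L) stop_config("num_classes must be >= 2")
  plan <- backbone_plan(backbone)
  branch_channels <- as.integer(branch_channels %||% (plan$deep_ch %/% 4L))
  head_channels <- as.integer(head_channels %||% branch_channels)
  structure(list(num_classes = as.integer(num_classes),
                 input_side = as.integer(input_side),
                 bins = bins, branch_channels = branch_channels,
                 head_channels = head_channels, dropout = dropout,
                 backbone = backbone, ca_enabled = isTRUE(ca_enabled),
                 ca_reduction = as.integer(ca_reduction),
                 ca_activation = ca_activation,
                 align_corners = isTRUE(align_corners)),
            class = "network_config")
}

#' Instantiate the segmentation network
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for deterministic initialisation.
#' @return List with class `capseg_net`: `cfg`, `plan`, `ca`, `params`
#'   (flat named list of arrays), `buffers` (environment of running
#'   batch-norm statistics).
#' @export
make_network <- function(cfg = network_config(), seed = 1L) {
  local_seed(seed, {
    b <- new_builder()
    plan <- build_backbone_params(b, cfg$backbone)
    ca <- NULL
    if (cfg$ca_enabled) {
      ca <- list(ca1 = attention_config(plan$stem_ch, cfg$ca_reduction,
                                        cfg$ca_activation),
                 ca2 = attention_config(plan$deep_ch, cfg$ca_reduction,
                                        cfg$ca_activation))
      build_ca_params(b, "ca1", ca$ca1)
      build_ca_params(b, "ca2", ca$ca2)
    }
    for (k in seq_along(cfg$bins)) {
      nm <- sprintf("ppm.branch%d", k)
      add_conv(b, paste0(nm, ".conv"), cfg$branch_channels, plan$deep_ch)
      add_bn(b, paste0(nm, ".bn"), cfg$branch_channels)
    }
    fused <- plan$deep_ch + length(cfg$bins) * cfg$branch_channels
    add_conv(b, "head.conv", cfg$head_channels, fused, 3L, 3L)
    add_bn(b, "head.bn", cfg$head_channels)
    add_conv(b, "classifier", cfg$num_classes, cfg$head_channels, bias = TRUE)
    structure(list(cfg = cfg, plan = plan, ca = ca, params = b$params,
                   buffers = params_to_env(b$buffers),
                   cache = new.env(parent = emptyenv())),
              class = "capseg_net")
  })
}

forward_ppm <- function(tape, deep, cfg, align) {
  d <- dim(deep$val)
  hd <- d[2]; wd <- d[3]
  if (any(cfg$bins > min(hd, wd)))
    stop_config("pyramid bin %d exceeds deep spatial side %d",
                max(cfg$bins), min(hd, wd))
  branches <- list(deep)
  for (k in seq_along(cfg$bins)) {
    nm <- sprintf("ppm.branch%d", k)
    p <- op_adapt_pool(tape, deep, cfg$bins[k], cfg$bins[k])
    p <- op_conv(tape, p, paste0(nm, ".conv"))
    p <- op_bn(tape, p, paste0(nm, ".bn"))
    p <- op_act(tape, p, "relu")
    p <- op_bilinear(tape, p, hd, wd, align)
    branches[[k + 1L]] <- p
  }
  h <- op_concat_ch(tape, branches)
  h <- op_conv(tape, h, "head.conv", pad = 1L)
  h <- op_bn(tape, h, "head.bn")
  h <- op_act(tape, h, "relu")
  op_dropout(tape, h, cfg$dropout)
}

forward_network <- function(tape, images, net) {
  S <- dim(images$val)[2]
  bb <- forward_backbone(tape, images, net$plan, net$ca)
  h <- forward_ppm(tape, bb$deep, net$cfg, net$cfg$align_corners)
  logits_ds <- op_conv(tape, h, "classifier", bias = TRUE)
  op_bilinear(tape, logits_ds, S, dim(images$val)[3], net$cfg$align_corners)
}

softmax_ch <- function(logits) {
  d <- dim(logits)
  K <- d[1]
  L <- matrix(logits, nrow = K)
  mx <- L[1, ]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, L[k, ])
  L <- exp(L - rep(mx, each = K))
  P <- L / rep(colSums(L), each = K)
  dim(P) <- d
  P
}

#' Pyramid pooling head forward pass
#'
#' Adaptive-average-pools the deep feature map to each pyramid grid,
#' compresses each with a 1x1 convolution + normalisation + ReLU, upsamples
#' bilinearly back to the deep resolution, concatenates all branches with
#' the deep map itself, and fuses with a 3x3 convolution (+ norm, ReLU,
#' dropout).
#'
#' @param deep Deep feature map `c(C, H, W)` or `c(C, H, W, N)`.
#' @param net A [make_network()] object.
#' @param training Logical; training-mode statistics and dropout.
#' @return Head feature map, same spatial size as `deep`.
#' @export
ppm_forward <- function(deep, net, training = FALSE) {
  single <- length(dim(deep)) == 3L
  deep <- as_chwn(deep, "deep features")
  tape <- new_tape(net$params, net$buffers, training = training)
  h <- forward_ppm(tape, op_input(tape, deep), net$cfg, net$cfg$align_corners)
  y <- h$val
  if (single) dim(y) <- dim(y)[1:3]
  y
}

#' Full segmentation forward pass
#'
#' @param images Array `c(3, S, S)` or `c(3, S, S, N)` of normalised images.
#' @param net A [make_network()] object.
#' @param training Logical; training-mode batch-norm and dropout.
#' @return List with `logits` and `probs` (per-pixel softmax over classes),
#'   shaped `c(K, S, S[, N])` matching the input rank.
#' @export
segment_forward <- function(images, net, training = FALSE) {
  single <- length(dim(images)) == 3L
  images <- as_chwn(images, "images")
  if (dim(images)[1] != 3L)
    stop_invalid("images must have 3 channels, got %d", dim(images)[1])
  tape <- new_tape(net$params, net$buffers, training = training)
  logits <- forward_network(tape, op_input(tape, images), net)
  probs <- softmax_ch(logits$val)
  lv <- logits$val
  if (single) {
    dim(lv) <- dim(lv)[1:3]
    dim(probs) <- dim(probs)[1:3]
  }
  list(logits = lv, probs = probs)
}

#' Count learnable parameters
#'
#' Sums every learnable scalar (convolution weights and biases,
#' normalisation scales and shifts; running statistics are not learnable).
#'
#' @param x A [make_network()] object or a [network_config()].
#' @return Integer total.
#' @seealso [parameter_breakdown()]
#' @export
count_parameters <- function(x) {
  if (inherits(x, "network_config")) x <- make_network(x, seed = 1L)
  if (inherits(x, "capseg_backbone") || inherits(x, "capseg_net"))
    return(as.integer(count_params_list(x$params)))
  stop_config("count_parameters expects a network, backbone, or config")
}

#' Per-module parameter breakdown
#'
#' @param net A [make_network()] object.
#' @return Named integer vector: backbone, ca1, ca2, ppm, head, classifier,
#'   total.
#' @export
parameter_breakdown <- function(net) {
  p <- net$params
  out <- c(backbone = count_params_list(p, "backbone."),
           ca1 = count_params_list(p, "ca1."),
           ca2 = count_params_list(p, "ca2."),
           ppm = count_params_list(p, "ppm."),
           head = count_params_list(p, "head."),
           classifier = count_params_list(p, "classifier"))
  as.integer(c(out, total = sum(out))) |> stats::setNames(c(names(out), "total"))
}
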