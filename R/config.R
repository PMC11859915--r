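#' Read / write a full configuration as YAML
#'
#' The YAML mirrors the configuration objects: top-level engine fields plus
#' `net:` (with nested `backbone:`) and `loss:` blocks. Missing fields fall
#' back to the package defaults.
#'
#' @param path YAML file.
#' @return `read_config` returns a [train_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io("no config file at '%s'", path)
  y <- yaml::read_yaml(path) %||% list()
  bb <- y$net$backbone %||% list()
  backbone <- backbone_config(width = bb$width %||% 1.0,
                              output_stride = as.integer(bb$output_stride %||% 8L))
  nn <- y$net %||% list()
  net <- network_config(
    num_classes = as.integer(nn$num_classes %||% 2L),
    input_side = as.integer(nn$input_side %||% 473L),
    bins = as.integer(nn$bins %||% c(1L, 2L, 3L, 6L)),
    branch_channels = nn$branch_channels,
    head_channels = nn$head_channels,
    dropout = nn$dropout %||% 0.1,
    backbone = backbone,
    ca_enabled = nn$ca$enabled %||% TRUE,
    ca_reduction = as.integer(nn$ca$reduction %||% 16L),
    ca_activation = nn$ca$activation %||% "hswish",
    align_corners = nn$align_corners %||% TRUE)
  ll <- y$loss %||% list()
  loss <- loss_config(lambda = ll$lambda %||% 0.6,
                      alpha = ll$alpha %||% 0.25,
                      gamma = ll$gamma %||% 2,
                      eps = ll$eps %||% 1e-5,
                      dice_mode = ll$dice_mode %||% "batch")
  train_config(epochs = as.integer(y$epochs %||% 150L),
               batch_size = as.integer(y$batch_size %||% 8L),
               lr = y$lr %||% 0.01,
               momentum = y$momentum %||% 0.9,
               weight_decay = y$weight_decay %||% 1e-4,
               poly_power = y$poly_power %||% 0.9,
               seed = as.integer(y$seed %||% 1L),
               augment = y$augment %||% TRUE,
               net = net, loss = loss)
}

#' @rdname read_config
#' @param cfg A [train_config()].
#' @export
write_config <- function(cfg, path) {
  y <- list(
    epochs = cfg$epochs, batch_size = cfg$batch_size, lr = cfg$lr,
    momentum = cfg$momentum, weight_decay = cfg$weight_decay,
    poly_power = cfg$poly_power, seed = cfg$seed, augment = cfg$augment,
    net = list(num_classes = cfg$net$num_classes,
               input_side = cfg$net$input_side, bins = cfg$net$bins,
               branch_channels = cfg$net$branch_channels,
               head_channels = cfg$net$head_channels,
               dropout = cfg$net$dropout,
               align_corners = cfg$net$align_corners,
               ca = list(enabled = cfg$net$ca_enabled,
                         reduction = cfg$net$ca_reduction,
                         activation = cfg$net$ca_activation),
               backbone = list(name = "mobilenetv2",
                               width = cfg$net$backbone$width,
                               output_stride = cfg$net$backbone$output_stride)),
    loss = unclass(cfg$loss))
  yaml::write_yaml(y, path)
  invisible(path)
}
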