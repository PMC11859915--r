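# Parameter initialisation and the named-parameter builder.
#
# A model is a flat named list of arrays (`params`) plus an environment of
# batch-norm running statistics (`buffers`). Builders append entries under
# hierarchical names ("backbone.stem.conv.w", "ca2.squeeze.b", ...), which
# also drive the per-module parameter accounting.

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$params <- list()
  b$buffers <- list()
  b
}

# He-normal fan-in initialisation; depthwise filters use groups = cin.
add_conv <- function(b, name, cout, cin, kh = 1L, kw = 1L, bias = FALSE,
                     groups = 1L) {
  fan_in <- (cin / groups) * kh * kw
  w <- array(stats::rnorm(cout * (cin / groups) * kh * kw,
                          sd = sqrt(2 / fan_in)),
             c(cout, cin / groups, kh, kw))
  b$params[[paste0(name, ".w")]] <- w
  if (bias) b$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(b)
}

add_bn <- function(b, name, C) {
  b$params[[paste0(name, ".gamma")]] <- rep(1, C)
  b$params[[paste0(name, ".beta")]] <- numeric(C)
  b$buffers[[paste0(name, ".running_mean")]] <- numeric(C)
  b$buffers[[paste0(name, ".running_var")]] <- rep(1, C)
  invisible(b)
}

params_to_env <- function(buffers) {
  e <- new.env(parent = emptyenv())
  for (nm in names(buffers)) e[[nm]] <- buffers[[nm]]
  e
}

buffers_to_list <- function(env) {
  nms <- ls(env)
  # deep copies: the training executor updates running statistics in place
  stats::setNames(lapply(nms, function(n) env[[n]] + 0), nms)
}

count_params_list <- function(params, prefix = NULL) {
  nms <- names(params)
  if (!is.null(prefix)) nms <- nms[startsWith(nms, prefix)]
  sum(vapply(params[nms], length, numeric(1)))
}
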