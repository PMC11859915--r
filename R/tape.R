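# Minimal reverse-mode tape over the layer primitives.
#
# A tensor on the tape is list(id, val); every op records a backward closure
# that maps the output gradient to input gradients and accumulates parameter
# gradients into tape$grads by name. tp_backward() walks the tape in reverse.

new_tape <- function(params, buffers, training = FALSE, pool = NULL) {
  tape <- new.env(parent = emptyenv())
  tape$params <- params
  tape$buffers <- buffers   # environment: running BN stats, updated in place
  tape$grads <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape$training <- isTRUE(training)
  tape$pool <- pool         # optional buffer pool shared across iterations
  tape$pk <- 0L
  tape
}

# Take the next slot from the tape's buffer pool. Identical graphs request
# identical slot sequences, so a pool created once is reused every
# iteration and steady-state training allocates almost nothing.
pool_take <- function(tape, len) {
  if (is.null(tape$pool)) return(numeric(0))
  tape$pk <- tape$pk + 1L
  key <- as.character(tape$pk)
  buf <- tape$pool[[key]]
  if (is.null(buf) || length(buf) != len) {
    buf <- numeric(len)
    tape$pool[[key]] <- buf
  }
  buf
}

tp_push <- function(tape, val, inputs = integer(0), backward = NULL) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- list(inputs = inputs, backward = backward)
  list(id = tape$n, val = val)
}

tp_param <- function(tape, name) {
  p <- tape$params[[name]]
  if (is.null(p)) stop_config("missing parameter '%s'", name)
  p
}

acc_grad <- function(tape, name, g) {
  cur <- tape$grads[[name]]
  tape$grads[[name]] <- if (is.null(cur)) g else cur + g
}

tp_backward <- function(tape, out, gout) {
  gtab <- vector("list", tape$n)
  gtab[[out$id]] <- gout
  for (id in seq(tape$n, 1L)) {
    node <- tape$nodes[[id]]
    g <- gtab[[id]]
    gtab[id] <- list(NULL)  # release
    if (is.null(g) || is.null(node$backward)) next
    gs <- node$backward(g)
    for (k in seq_along(node$inputs)) {
      if (is.null(gs[[k]])) next
      i <- node$inputs[k]
      gtab[[i]] <- if (is.null(gtab[[i]])) gs[[k]] else gtab[[i]] + gs[[k]]
    }
  }
  invisible(NULL)
}

op_input <- function(tape, x) tp_push(tape, x)

op_conv <- function(tape, x, name, stride = 1L, pad = 0L, dil = 1L,
                    bias = FALSE) {
  w <- tp_param(tape, paste0(name, ".w"))
  b <- if (bias) tp_param(tape, paste0(name, ".b")) else numeric(0)
  xv <- x$val
  d <- dim(xv)
  ylen <- prod(conv_out_shape(d, dim(w), stride, pad, dil))
  y <- cpp_conv_fwd(xv, d, w, dim(w), b, stride, pad, dil,
                    pool_take(tape, ylen))
  tp_push(tape, y, x$id, function(gy) {
    gr <- cpp_conv_bwd(xv, d, w, dim(w), gy, bias, stride, pad, dil,
                       pool_take(tape, length(xv)))
    acc_grad(tape, paste0(name, ".w"), gr$gw)
    if (bias) acc_grad(tape, paste0(name, ".b"), gr$gb)
    list(gr$gx)
  })
}

op_dwconv <- function(tape, x, name, stride = 1L, pad = 1L, dil = 1L) {
  w <- tp_param(tape, paste0(name, ".w"))
  kh <- dim(w)[3]; kw <- dim(w)[4]
  xv <- x$val
  d <- dim(xv)
  ylen <- prod(conv_out_shape(d, c(d[1], 1L, kh, kw), stride, pad, dil))
  y <- cpp_dwconv_fwd(xv, d, w, kh, kw, stride, pad, dil,
                      pool_take(tape, ylen))
  tp_push(tape, y, x$id, function(gy) {
    gr <- cpp_dwconv_bwd(xv, d, w, kh, kw, gy, stride, pad, dil,
                         pool_take(tape, length(xv)))
    acc_grad(tape, paste0(name, ".w"), gr$gw)
    list(gr$gx)
  })
}

op_bn <- function(tape, x, name, eps = 1e-5, momentum = 0.1) {
  gamma <- tp_param(tape, paste0(name, ".gamma"))
  beta <- tp_param(tape, paste0(name, ".beta"))
  xv <- x$val
  d <- dim(xv)
  C <- d[1]
  m <- length(xv) / C
  if (tape$training) {
    st <- cpp_bn_stats(xv, d)
    mu <- st$mean
    v <- st$var
    rk <- paste0(name, ".running_mean")
    vk <- paste0(name, ".running_var")
    unb <- if (m > 1) v * m / (m - 1) else v
    tape$buffers[[rk]] <- (1 - momentum) * tape$buffers[[rk]] + momentum * mu
    tape$buffers[[vk]] <- (1 - momentum) * tape$buffers[[vk]] + momentum * unb
  } else {
    mu <- tape$buffers[[paste0(name, ".running_mean")]]
    v <- tape$buffers[[paste0(name, ".running_var")]]
  }
  invstd <- 1 / sqrt(v + eps)
  y <- cpp_bn_apply(xv, d, gamma, beta, mu, invstd, pool_take(tape, length(xv)))
  training <- tape$training
  tp_push(tape, y, x$id, function(gy) {
    gr <- cpp_bn_bwd(xv, d, gamma, mu, invstd, gy, training)
    acc_grad(tape, paste0(name, ".gamma"), gr$dgamma)
    acc_grad(tape, paste0(name, ".beta"), gr$dbeta)
    list(gr$gx)
  })
}

act_kind <- c(relu = 0L, relu6 = 1L, hswish = 2L, sigmoid = 3L)

# Activations run in place where the backward needs only the output
# (relu/relu6/sigmoid): the input tensor is always the single-consumer
# output of the preceding conv/bn node, whose backward never reads it.
op_act <- function(tape, x, kind) {
  k <- act_kind[[kind]]
  if (is.null(k)) stop_config("unknown activation '%s'", kind)
  if (kind == "hswish") {
    xv <- x$val
    y <- cpp_act_fwd(xv, k)
    return(tp_push(tape, y, x$id, function(gy) {
      list(cpp_act_bwd(xv, y, gy, k))
    }))
  }
  y <- cpp_act_fwd_ip(x$val, k)
  tp_push(tape, y, x$id, function(gy) {
    list(cpp_act_bwd_ip(y, gy, k))
  })
}

op_add <- function(tape, a, b) {
  # the two returned gradients must not alias: downstream backwards may
  # mutate their gradient in place
  tp_push(tape, a$val + b$val, c(a$id, b$id),
          function(gy) list(gy, gy + 0))
}

op_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) {
    return(tp_push(tape, x$val, x$id, function(gy) list(gy)))
  }
  keep <- (stats::runif(length(x$val)) >= rate) / (1 - rate)
  y <- x$val * keep
  dim(y) <- dim(x$val)
  tp_push(tape, y, x$id, function(gy) {
    g <- gy * keep
    dim(g) <- dim(x$val)
    list(g)
  })
}

# Concatenate along the channel dimension (dim 1).
op_concat_ch <- function(tape, xs) {
  ds <- lapply(xs, function(t) dim(t$val))
  cs <- vapply(ds, `[`, integer(1), 1L)
  d0 <- ds[[1]]
  y <- array(0, c(sum(cs), d0[2], d0[3], d0[4]))
  at <- 0L
  for (k in seq_along(xs)) {
    y[at + seq_len(cs[k]), , , ] <- xs[[k]]$val
    at <- at + cs[k]
  }
  tp_push(tape, y, vapply(xs, `[[`, integer(1), "id"), function(gy) {
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      g <- gy[at + seq_len(cs[k]), , , , drop = FALSE]
      out[[k]] <- g
      at <- at + cs[k]
    }
    out
  })
}

# Concatenate two c(C, L, 1, N) strips along dim 2 (used by the CA block).
op_concat2 <- function(tape, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1], da[2] + db[2], 1L, da[4]))
  y[, seq_len(da[2]), 1, ] <- a$val
  y[, da[2] + seq_len(db[2]), 1, ] <- b$val
  tp_push(tape, y, c(a$id, b$id), function(gy) {
    list(gy[, seq_len(da[2]), , , drop = FALSE],
         gy[, da[2] + seq_len(db[2]), , , drop = FALSE])
  })
}

op_slice2 <- function(tape, x, from, to) {
  d <- dim(x$val)
  y <- x$val[, from:to, , , drop = FALSE]
  tp_push(tape, y, x$id, function(gy) {
    g <- array(0, d)
    g[, from:to, , ] <- gy
    list(g)
  })
}

op_bilinear <- function(tape, x, oh, ow, align = TRUE) {
  xv <- x$val
  d <- dim(xv)
  y <- cpp_bilinear_fwd(xv, d, oh, ow, align,
                        pool_take(tape, d[1] * oh * ow * d[4]))
  tp_push(tape, y, x$id, function(gy) {
    list(cpp_bilinear_bwd(gy, dim(y), d[2], d[3], align,
                          pool_take(tape, length(xv))))
  })
}

op_adapt_pool <- function(tape, x, oh, ow) {
  xv <- x$val
  d <- dim(xv)
  y <- cpp_adapt_pool_fwd(xv, d, oh, ow,
                          pool_take(tape, d[1] * oh * ow * d[4]))
  tp_push(tape, y, x$id, function(gy) {
    list(cpp_adapt_pool_bwd(gy, dim(y), d[2], d[3],
                            pool_take(tape, length(xv))))
  })
}

# Strip means: over width -> c(C,H,1,N); over height -> c(C,W,1,N).
op_mean_w <- function(tape, x) {
  d <- dim(x$val)
  y <- cpp_mean_w(x$val, d)
  tp_push(tape, y, x$id, function(gy) {
    g3 <- array(gy, c(d[1], d[2], d[4]))
    g <- aperm(array(g3, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)) / d[3]
    list(g)
  })
}

op_mean_h <- function(tape, x) {
  d <- dim(x$val)
  y <- cpp_mean_h(x$val, d)
  tp_push(tape, y, x$id, function(gy) {
    g3 <- array(gy, c(d[1], d[3], d[4]))  # C, W, N
    g <- aperm(array(g3, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3)) / d[2]
    list(g)
  })
}

# y[c,h,w,n] = x[c,h,w,n] * gh[c,h,1,n] * gw[c,w,1,n]
op_scale_hw <- function(tape, x, gh, gw) {
  xv <- x$val; hv <- gh$val; wv <- gw$val
  y <- cpp_scale_hw_fwd(xv, dim(xv), hv, wv, pool_take(tape, length(xv)))
  tp_push(tape, y, c(x$id, gh$id, gw$id), function(gy) {
    gr <- cpp_scale_hw_bwd(xv, dim(xv), hv, wv, gy,
                           pool_take(tape, length(xv)))
    list(gr$gx, gr$ggh, gr$ggw)
  })
}

# Output dims of a convolution: c(Cout, OH, OW, N)
conv_out_shape <- function(xd, wd, stride, pad, dil) {
  oh <- (xd[2] + 2 * pad - ((wd[3] - 1) * dil + 1)) %/% stride + 1
  ow <- (xd[3] + 2 * pad - ((wd[4] - 1) * dil + 1)) %/% stride + 1
  c(wd[1], oh, ow, xd[4])
}
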