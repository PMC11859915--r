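# Compiler from the network plan to the single-precision executor program.
#
# The program mirrors forward_network()/forward_ca()/forward_ppm() exactly;
# the double-precision tape remains the reference implementation and the
# tests cross-check the two on identical inputs.

OPC <- c(conv = 0L, dwconv = 1L, bn = 2L, act = 3L, add = 4L, meanw = 5L,
         meanh = 6L, concat2 = 7L, slice2 = 8L, scalehw = 9L,
         concatch = 10L, adaptpool = 11L, bilinear = 12L, dropout = 13L)

vm_program <- function(net, N, S) {
  pnames <- names(net$params)
  bnames <- ls(net$buffers)
  dims <- list()
  instrs <- list()
  tid <- 0L
  new_t <- function(d) {
    tid <<- tid + 1L
    dims[[tid]] <<- as.integer(d)
    tid - 1L  # 0-based ids for C++
  }
  pidx <- function(name) {
    i <- match(name, pnames)
    if (is.na(i)) stop_config("vm: unknown parameter '%s'", name)
    i - 1L
  }
  bidx <- function(name) {
    i <- match(name, bnames)
    if (is.na(i)) stop_config("vm: unknown buffer '%s'", name)
    i - 1L
  }
  dim_of <- function(id) dims[[id + 1L]]
  emit <- function(op, ins, out, g = c(1L, 1L, 1L, 0L, 1L, 0L), kind = 0L,
                   from = 0L, len = 0L, oh = 0L, ow = 0L, align = 1L,
                   rate = 0, pw = -1L, pb = -1L, bm = -1L, bv = -1L) {
    instrs[[length(instrs) + 1L]] <<- list(
      op = OPC[[op]], ins = as.integer(ins), out = as.integer(out),
      g = as.integer(g), kind = as.integer(kind), from = as.integer(from),
      len = as.integer(len), oh = as.integer(oh), ow = as.integer(ow),
      align = as.integer(align), rate = as.numeric(rate),
      pw = as.integer(pw), pb = as.integer(pb), bm = as.integer(bm),
      bv = as.integer(bv))
    out
  }
  r_conv <- function(x, name, stride = 1L, pad = 0L, dil = 1L,
                     bias = FALSE) {
    w <- net$params[[paste0(name, ".w")]]
    od <- conv_out_shape(dim_of(x), dim(w), stride, pad, dil)
    emit("conv", x, new_t(od),
         g = c(dim(w)[3], dim(w)[4], stride, pad, dil, as.integer(bias)),
         pw = pidx(paste0(name, ".w")),
         pb = if (bias) pidx(paste0(name, ".b")) else -1L)
  }
  r_dwconv <- function(x, name, stride = 1L, pad = 1L, dil = 1L) {
    w <- net$params[[paste0(name, ".w")]]
    d <- dim_of(x)
    od <- conv_out_shape(d, c(d[1], 1L, dim(w)[3], dim(w)[4]), stride, pad,
                         dil)
    emit("dwconv", x, new_t(od),
         g = c(dim(w)[3], dim(w)[4], stride, pad, dil, 0L),
         pw = pidx(paste0(name, ".w")))
  }
  r_bn <- function(x, name) {
    emit("bn", x, new_t(dim_of(x)),
         pw = pidx(paste0(name, ".gamma")), pb = pidx(paste0(name, ".beta")),
         bm = bidx(paste0(name, ".running_mean")),
         bv = bidx(paste0(name, ".running_var")))
  }
  r_act <- function(x, kind) {
    emit("act", x, new_t(dim_of(x)), kind = act_kind[[kind]])
  }
  r_ca <- function(x, prefix, cfg) {
    d <- dim_of(x)
    H <- d[2]; W <- d[3]
    zh <- emit("meanw", x, new_t(c(d[1], H, 1L, d[4])))
    zw <- emit("meanh", x, new_t(c(d[1], W, 1L, d[4])))
    f <- emit("concat2", c(zh, zw), new_t(c(d[1], H + W, 1L, d[4])))
    f <- r_conv(f, paste0(prefix, ".squeeze"), bias = TRUE)
    f <- r_bn(f, paste0(prefix, ".norm"))
    f <- r_act(f, cfg$activation)
    hid <- dim_of(f)[1]
    fh <- emit("slice2", f, new_t(c(hid, H, 1L, d[4])), from = 0L, len = H)
    fw <- emit("slice2", f, new_t(c(hid, W, 1L, d[4])), from = H, len = W)
    gh <- r_act(r_conv(fh, paste0(prefix, ".fh"), bias = TRUE), "sigmoid")
    gw <- r_act(r_conv(fw, paste0(prefix, ".fw"), bias = TRUE), "sigmoid")
    emit("scalehw", c(x, gh, gw), new_t(d))
  }

  x <- new_t(c(3L, S, S, N)) # input = tensor 0
  t <- r_conv(x, "backbone.stem.conv", stride = 2L, pad = 1L)
  t <- r_bn(t, "backbone.stem.bn")
  t <- r_act(t, "relu6")
  if (!is.null(net$ca)) t <- r_ca(t, "ca1", net$ca$ca1)
  for (blk in net$plan$blocks) {
    xin <- t
    if (blk$exp != blk$cin) {
      t <- r_conv(t, paste0(blk$name, ".expand"))
      t <- r_bn(t, paste0(blk$name, ".expand_bn"))
      t <- r_act(t, "relu6")
    }
    t <- r_dwconv(t, paste0(blk$name, ".dw"), stride = blk$stride,
                  pad = blk$dil, dil = blk$dil)
    t <- r_bn(t, paste0(blk$name, ".dw_bn"))
    t <- r_act(t, "relu6")
    t <- r_conv(t, paste0(blk$name, ".project"))
    t <- r_bn(t, paste0(blk$name, ".project_bn"))
    if (blk$use_res) t <- emit("add", c(t, xin), new_t(dim_of(t)))
  }
  if (!is.null(net$ca)) t <- r_ca(t, "ca2", net$ca$ca2)
  deep <- t
  dd <- dim_of(deep)
  hd <- dd[2]; wd <- dd[3]
  cfg <- net$cfg
  if (any(cfg$bins > min(hd, wd)))
    stop_config("pyramid bin %d exceeds deep spatial side %d",
                max(cfg$bins), min(hd, wd))
  branches <- deep
  for (k in seq_along(cfg$bins)) {
    nm <- sprintf("ppm.branch%d", k)
    p <- emit("adaptpool", deep,
              new_t(c(dd[1], cfg$bins[k], cfg$bins[k], dd[4])),
              oh = cfg$bins[k], ow = cfg$bins[k])
    p <- r_conv(p, paste0(nm, ".conv"))
    p <- r_bn(p, paste0(nm, ".bn"))
    p <- r_act(p, "relu")
    p <- emit("bilinear", p, new_t(c(cfg$branch_channels, hd, wd, dd[4])),
              oh = hd, ow = wd, align = as.integer(cfg$align_corners))
    branches <- c(branches, p)
  }
  csum <- sum(vapply(branches, function(id) dim_of(id)[1], integer(1)))
  h <- emit("concatch", branches, new_t(c(csum, hd, wd, dd[4])))
  h <- r_conv(h, "head.conv", pad = 1L)
  h <- r_bn(h, "head.bn")
  h <- r_act(h, "relu")
  h <- emit("dropout", h, new_t(dim_of(h)), rate = cfg$dropout)
  lg <- r_conv(h, "classifier", bias = TRUE)
  lg <- emit("bilinear", lg, new_t(c(cfg$num_classes, S, S, N)),
             oh = S, ow = S, align = as.integer(cfg$align_corners))
  list(instrs = instrs, dims = do.call(rbind, dims), logits = lg,
       pnames = pnames, bnames = bnames)
}

vm_get <- function(net, N, S) {
  key <- sprintf("vm_%d_%d", N, S)
  vm <- net$cache[[key]]
  if (!is.null(vm)) return(vm)
  prog <- vm_program(net, N, S)
  ptr <- cpp_vm_new(prog$instrs, prog$dims,
                    vapply(net$params, length, integer(1)), prog$logits)
  vm <- list(ptr = ptr, pnames = prog$pnames, bnames = prog$bnames,
             S = S, N = N)
  net$cache[[key]] <- vm
  vm
}

vm_buffers <- function(net, vm) {
  lapply(vm$bnames, function(n) net$buffers[[n]])
}

vm_forward_logits <- function(net, x, training = FALSE) {
  d <- dim(x)
  vm <- vm_get(net, d[4], d[2])
  cpp_vm_forward(vm$ptr, net$params, vm_buffers(net, vm), x, training)
}
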