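`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("capseg_invalid_input", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("capseg_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("capseg_io_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls do not perturb user RNG.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce a feature map to the internal batched layout c(C, H, W, N).
as_chwn <- function(x, what = "input") {
  if (!is.numeric(x)) stop_invalid("%s must be a numeric array", what)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop_invalid("%s must have dim c(C,H,W) or c(C,H,W,N)", what)
  if (any(d < 1L)) stop_invalid("%s has an empty dimension", what)
  if (any(!is.finite(x))) stop_invalid("%s contains non-finite values", what)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

fmt_pct <- function(x) sprintf("%.2f", x)
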