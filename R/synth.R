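# Synthetic lesion-image generator.
#
# Emulates the three regimes of 2-D medical segmentation data the pipeline
# targets without any download: small targets (lesions under 1% of image
# area), fuzzy boundaries (Gaussian-blurred lesion edges), and noisy
# background texture. Lesions are unions of randomly placed, randomly
# oriented ellipses whose outline radius is perturbed by a low-order
# Fourier series (amplitude <= 0.3 of the radius), giving irregular but
# simply connected blobs resembling lesions/polyps.

#' Synthetic dataset configuration
#'
#' @param n_images Number of image/mask pairs.
#' @param side Image side S in pixels. The desk-test default 97 is stride-8
#'   compatible (96/8 + 1 = 13) and keeps CPU training in the minutes.
#' @param n_lesions Integer range `c(min, max)` of lesions per image.
#' @param area_frac Range of the total foreground area fraction per image;
#'   must sit inside (0, 0.5).
#' @param contrast Foreground intensity offset on the 0-255 scale.
#' @param blur_sigma Gaussian blur (pixels) applied to the lesion edge in
#'   the image; 0 keeps a hard boundary. The mask itself stays binary.
#' @param noise_sd Per-pixel Gaussian noise standard deviation (0-255
#'   scale).
#' @param texture_sd Amplitude of the smooth background texture.
#' @param base Mean background intensity.
#' @param ratios Train/val/test weights for the returned index.
#' @param seed Integer seed; the generated dataset is byte-identical for a
#'   given configuration and seed.
#' @param preset One of `"easy"` (high contrast = 5x noise sd, hard
#'   boundary), `"small-target"` (total lesion area under 1% of the image)
#'   or `"fuzzy-boundary"` (edge blur >= 2 px); overrides the related
#'   fields.
#' @return List with class `synth_config`.
#' @export
synth_config <- function(n_images = 200L, side = 97L,
                         n_lesions = c(1L, 3L), area_frac = c(0.05, 0.15),
                         contrast = 60, blur_sigma = 0, noise_sd = 12,
                         texture_sd = 3, base = 90, ratios = c(8, 1, 1),
                         seed = 1L, preset = NULL) {
  cfg <- list(n_images = as.integer(n_images), side = as.integer(side),
              n_lesions = as.integer(n_lesions), area_frac = area_frac,
              contrast = contrast, blur_sigma = blur_sigma,
              noise_sd = noise_sd, texture_sd = texture_sd, base = base,
              ratios = ratios, seed = as.integer(seed),
              preset = preset %||% "custom")
  if (!is.null(preset)) {
    cfg <- switch(preset,
      "easy" = within_list(cfg, area_frac = c(0.05, 0.15), contrast = 60,
                           blur_sigma = 0, noise_sd = 12),
      "small-target" = within_list(cfg, area_frac = c(0.001, 0.01),
                                   n_lesions = c(1L, 2L)),
      "fuzzy-boundary" = within_list(cfg, blur_sigma = 2.5),
      stop_config("unknown preset '%s'", preset))
  }
  if (cfg$area_frac[1] <= 0 || cfg$area_frac[2] >= 0.5)
    stop_config("area fraction range must sit inside (0, 0.5)")
  if (cfg$area_frac[1] * cfg$side^2 < 4)
    stop_config("area range infeasible for side %d: smallest lesion < 4 px",
                cfg$side)
  structure(cfg, class = "synth_config")
}

within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

# Binary lesion mask for one ellipse: centre (cy, cx), semi-axes (a, b),
# orientation phi, radial perturbation rho(theta).
ellipse_mask <- function(side, cy, cx, a, b, phi, pert) {
  r <- rep(seq_len(side), times = side) - cy
  c <- rep(seq_len(side), each = side) - cx
  u <- cos(phi) * r + sin(phi) * c
  v <- -sin(phi) * r + cos(phi) * c
  theta <- atan2(v, u)
  rho <- rep(1, length(theta))
  for (k in seq_along(pert$amp))
    rho <- rho + pert$amp[k] * cos((k + 1) * theta + pert$phase[k])
  inside <- (u / a)^2 + (v / b)^2 <= rho^2
  matrix(inside, side, side)
}

#' Generate one synthetic lesion mask
#'
#' Draws 1-3 perturbed ellipses and rescales their axes so that the
#' realised total foreground fraction lands within 20% (relative) of the
#' drawn target; for small-target configurations the fraction is
#' additionally forced below 1%.
#'
#' @param cfg A [synth_config()]. Uses the current RNG stream.
#' @return List: `mask` (side x side integer matrix in {0, 1}) and
#'   `area_frac` (realised foreground fraction).
#' @export
make_lesion_mask <- function(cfg) {
  side <- cfg$side
  target <- stats::runif(1, cfg$area_frac[1], cfg$area_frac[2])
  nles <- sample(seq(cfg$n_lesions[1], cfg$n_lesions[2]), 1)
  shares <- stats::runif(nles, 0.5, 1)
  shares <- shares / sum(shares)
  les <- vector("list", nles)
  for (i in seq_len(nles)) {
    area_px <- shares[i] * target * side^2
    r0 <- sqrt(area_px / pi)
    ecc <- stats::runif(1, 0.6, 1)
    a <- r0 / sqrt(ecc)
    b <- r0 * sqrt(ecc)
    margin <- max(a, b)
    les[[i]] <- list(
      cy = stats::runif(1, 1 + 0.6 * margin, side - 0.6 * margin),
      cx = stats::runif(1, 1 + 0.6 * margin, side - 0.6 * margin),
      a = a, b = b, phi = stats::runif(1, 0, pi),
      pert = list(amp = stats::runif(4, -0.075, 0.075),
                  phase = stats::runif(4, 0, 2 * pi)))
  }
  render <- function(scale) {
    m <- matrix(FALSE, side, side)
    for (l in les)
      m <- m | ellipse_mask(side, l$cy, l$cx, scale * l$a, scale * l$b,
                            l$phi, l$pert)
    m
  }
  scale <- 1
  m <- render(scale)
  for (it in 1:4) {
    realised <- mean(m)
    if (realised > 0 && abs(realised / target - 1) <= 0.05) break
    scale <- scale * sqrt(target / max(realised, 1 / side^2))
    m <- render(scale)
  }
  # small-target guarantee: keep strictly under 1% when the range asks for it
  if (cfg$area_frac[2] <= 0.01) {
    while (mean(m) >= 0.01) {
      scale <- scale * 0.9
      m <- render(scale)
    }
  }
  list(mask = matrix(as.integer(m), side, side), area_frac = mean(m))
}

# Smooth background texture: white noise blurred to low frequency.
smooth_noise <- function(side, sigma) {
  z <- matrix(stats::rnorm(side^2), side, side)
  EBImage::imageData(EBImage::gblur(z, sigma = sigma))
}

#' Generate a synthetic segmentation dataset on disk
#'
#' Each image is `base` + smooth background texture + `contrast` times the
#' (optionally edge-blurred) lesion mask + per-pixel Gaussian noise, clipped
#' to 0-255 and written as an 8-bit RGB PNG; masks are written as 8-bit
#' PNGs with values {0, 255}.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (`images/` and `masks/` are created).
#' @return A `dataset_index` (stem, image, mask, split, area_frac), also
#'   cached as `index.tsv` in `out_dir`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  side <- cfg$side
  af <- numeric(cfg$n_images)
  local_seed(cfg$seed, {
    for (i in seq_len(cfg$n_images)) {
      lm <- make_lesion_mask(cfg)
      af[i] <- lm$area_frac
      fg <- lm$mask
      fg_soft <- if (cfg$blur_sigma > 0)
        EBImage::imageData(EBImage::gblur(fg + 0, sigma = cfg$blur_sigma)) else fg
      # texture blur radius is capped so the Gaussian brush fits the image
      tex <- if (cfg$texture_sd > 0)
        cfg$texture_sd * smooth_noise(side, sigma = min(8, (side - 3) %/% 7))
      else 0
      img <- cfg$base + tex +
        cfg$contrast * fg_soft +
        matrix(stats::rnorm(side^2, sd = cfg$noise_sd), side, side)
      img <- pmin(pmax(img, 0), 255) / 255
      stem <- sprintf("synth%04d", i)
      png::writePNG(array(rep(img, 3), c(side, side, 3)),
                    file.path(out_dir, "images", paste0(stem, ".png")))
      write_mask_png(fg, file.path(out_dir, "masks", paste0(stem, ".png")))
    }
  })
  stems <- sprintf("synth%04d", seq_len(cfg$n_images))
  index <- split_dataset(
    data.frame(stem = stems,
               image = file.path(out_dir, "images", paste0(stems, ".png")),
               mask = file.path(out_dir, "masks", paste0(stems, ".png")),
               area_frac = af, stringsAsFactors = FALSE),
    ratios = cfg$ratios, seed = cfg$seed)
  write_index(index, file.path(out_dir, "index.tsv"))
  index
}
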