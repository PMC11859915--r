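# Dataset reading, preprocessing and splitting.
#
# Directory convention: <root>/images/*.png|jpg and <root>/masks/*.png with
# matching stems. Masks are single-channel 8-bit rasters with background 0
# and target 255; any value >= 128 is read as foreground (tolerates JPEG
# artefacts). The cached index is a TSV of (stem, image, mask, split).

read_image_array <- function(path) {
  if (!file.exists(path)) stop_io("cannot read image '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a) %||% numeric(0)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- a[, , c(1, 1, 1), drop = FALSE]
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a  # H x W x 3, values in [0, 1]
}

read_mask_array <- function(path) {
  if (!file.exists(path)) stop_io("cannot read mask '%s'", path)
  a <- read_image_array(path)
  a[, , 1]
}

#' Load and preprocess one image/mask pair
#'
#' The image is resized to `side x side` with bilinear interpolation and
#' normalised per channel to mean 0.5 / sd 0.5 (training is from scratch, so
#' the statistics are a free, fixed choice); the mask is resized with
#' nearest-neighbour (label-preserving) interpolation and remapped
#' 0/255 -> 0/1 (threshold 128).
#'
#' @param image_path,mask_path Paths to the image and its mask.
#' @param side Target side S in pixels (default 473).
#' @return Object of class `seg_sample`: `image` (`c(3, S, S)` array) and
#'   `mask` (`S x S` integer matrix in `{0, 1}`).
#' @export
load_pair <- function(image_path, mask_path, side = 473L) {
  img <- read_image_array(image_path)
  msk <- read_mask_array(mask_path)
  if (!all(dim(img)[1:2] == dim(msk)))
    stop_invalid("image %s and mask %s sizes disagree (%dx%d vs %dx%d)",
                 basename(image_path), basename(mask_path),
                 dim(img)[1], dim(img)[2], dim(msk)[1], dim(msk)[2])
  side <- as.integer(side)
  if (any(dim(msk) != side)) {
    img <- EBImage::resize(img, w = side, h = side, filter = "bilinear")
    msk <- EBImage::resize(msk, w = side, h = side, filter = "none")
  }
  mask <- matrix(as.integer(msk >= 128 / 255), side, side)
  image <- (aperm(img, c(3, 1, 2)) - 0.5) / 0.5
  structure(list(image = image, mask = mask), class = "seg_sample")
}

# Rotate paired (image, mask) by `angle` degrees about the centre, output
# size preserved: bilinear sampling with reflection padding for the image,
# nearest-neighbour for the mask so labels are never interpolated.
rotate_pair <- function(image, mask, angle) {
  r <- cpp_rotate_pair(image, dim(image), mask, nrow(mask), ncol(mask),
                       angle)
  list(image = r$image, mask = r$mask)
}

#' Randomly flip and rotate a sample
#'
#' Training-time augmentation: horizontal flip with probability 0.5,
#' vertical flip with probability 0.5, then rotation by an angle drawn
#' uniformly from `[-max_angle, max_angle]` degrees. Image and mask receive
#' the identical geometric transform; the mask is resampled with
#' nearest-neighbour and the image bilinearly with reflection padding.
#' Draws come from the current RNG stream (seed it for reproducibility).
#'
#' @param sample A `seg_sample` from [load_pair()].
#' @param max_angle Rotation half-range in degrees (default 30).
#' @param p_flip Per-axis flip probability (default 0.5).
#' @return Augmented `seg_sample`.
#' @export
augment_sample <- function(sample, max_angle = 30, p_flip = 0.5) {
  img <- sample$image
  msk <- sample$mask
  if (stats::runif(1) < p_flip) {  # horizontal: reverse columns
    img <- img[, , rev(seq_len(dim(img)[3])), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (stats::runif(1) < p_flip) {  # vertical: reverse rows
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  angle <- stats::runif(1, -max_angle, max_angle)
  if (angle != 0) {
    rp <- rotate_pair(img, msk, angle)
    img <- rp$image
    msk <- rp$mask
  }
  structure(list(image = img, mask = msk), class = "seg_sample")
}

#' Split records into train/validation/test sets
#'
#' Seeded uniform shuffle followed by contiguous assignment with
#' largest-remainder rounding of the target proportions (default 8:1:1
#' train:val:test, the conventional reading of a 1:1:8 test:val:train
#' ratio).
#'
#' @param records A data frame with a `stem` column (plus any path columns)
#'   or a character vector of stems.
#' @param ratios Numeric length-3 vector of train/val/test weights.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return The records as a data frame with a `split` column, class
#'   `dataset_index`.
#' @export
split_dataset <- function(records, ratios = c(8, 1, 1), seed = 1L) {
  if (is.character(records)) records <- data.frame(stem = records)
  n <- nrow(records)
  if (n < 10L) stop_config("need at least 10 records to split, got %d", n)
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop_config("ratios must be 3 non-negative weights")
  target <- n * ratios / sum(ratios)
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- local_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "val"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  records$split <- split
  structure(records, class = c("dataset_index", "data.frame"))
}

#' Build a dataset index from a directory
#'
#' Pairs `<root>/images/*` with `<root>/masks/*.png` by file stem.
#'
#' @param root Dataset directory.
#' @param ratios,seed Passed to [split_dataset()].
#' @return A `dataset_index` data frame (stem, image, mask, split).
#' @export
build_index <- function(root, ratios = c(8, 1, 1), seed = 1L) {
  imgs <- list.files(file.path(root, "images"), pattern = "\\.(png|jpe?g)$",
                     full.names = TRUE, ignore.case = TRUE)
  if (length(imgs) == 0L) stop_io("no images under %s/images", root)
  stems <- tools::file_path_sans_ext(basename(imgs))
  masks <- file.path(root, "masks", paste0(stems, ".png"))
  missing <- !file.exists(masks)
  if (any(missing))
    stop_invalid("missing mask for stem(s): %s",
                 paste(head(stems[missing], 3), collapse = ", "))
  split_dataset(data.frame(stem = stems, image = imgs, mask = masks,
                           stringsAsFactors = FALSE),
                ratios = ratios, seed = seed)
}

#' Write / read a dataset index as TSV
#' @param index A `dataset_index`.
#' @param path TSV file path.
#' @return `read_index` returns the `dataset_index`.
#' @export
write_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop_io("no index at '%s'", path)
  structure(utils::read.delim(path, stringsAsFactors = FALSE),
            class = c("dataset_index", "data.frame"))
}

#' Write a binary mask as an 8-bit PNG with values {0, 255}
#' @param mask Integer matrix in `{0, 1}`.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask == 1L), nrow(mask), ncol(mask)), path)
  invisible(path)
}
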