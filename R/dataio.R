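# ---------------------------------------------------------------------------
# Data loading: paired image/mask directories (images/ + masks/, matched by
# file stem), Lanczos rescaling to the model input size, mask binarization,
# and the reproducible 80:10:10 split.
# ---------------------------------------------------------------------------

#' Read an image file
#'
#' Supports PNG and JPEG (the codecs available in this environment). Returns
#' values in \[0, 1\]; palette/greyscale inputs are expanded and alpha is
#' dropped.
#'
#' @param path file path.
#' @return an (H, W, C) array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "' (PNG and JPEG are supported): ",
         path))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  img
}

to_rgb <- function(img) {
  d <- dim(img)
  if (d[3] >= 3L) return(img[, , 1:3, drop = FALSE])
  array(rep(img[, , 1], 3L), c(d[1], d[2], 3L))
}

collapse_gray <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (d[3] == 1L) img[, , 1] else apply(img[, , 1:min(3, d[3]), drop = FALSE],
                                        c(1, 2), max)
}

# Separable Lanczos-3 resampling with pixel-centre alignment. When
# downscaling, the kernel is widened by the scale factor (standard
# anti-aliased Lanczos).
lanczos_matrix <- function(n_in, n_out, a = 3) {
  scale <- n_in / n_out
  support <- a * max(1, scale)
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    lo <- max(1L, floor(src - support))
    hi <- min(n_in, ceiling(src + support))
    j <- lo:hi
    x <- (j - src) / max(1, scale)
    w <- ifelse(abs(x) < 1e-12, 1,
                ifelse(abs(x) >= a, 0,
                       a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2)))
    if (sum(w) == 0) w[which.min(abs(x))] <- 1
    W[i, j] <- w / sum(w)
  }
  W
}

#' Resize an image with Lanczos-3 resampling
#'
#' @param img (H, W) matrix or (H, W, C) array.
#' @param height,width output size in pixels.
#' @return resized matrix/array (not clipped).
#' @export
resize_lanczos <- function(img, height, width) {
  d <- dim(img)
  Wr <- lanczos_matrix(d[1], height)
  Wc <- lanczos_matrix(d[2], width)
  if (length(d) == 2L) return(Wr %*% img %*% t(Wc))
  out <- array(0, c(height, width, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% img[, , ch] %*% t(Wc)
  out
}

#' Resize with nearest-neighbour resampling (for masks)
#'
#' @inheritParams resize_lanczos
#' @return resized matrix.
#' @export
resize_nearest <- function(img, height, width) {
  d <- dim(img)
  ri <- pmin(pmax(ceiling((seq_len(height) - 0.5) * d[1] / height), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(width) - 0.5) * d[2] / width), 1L), d[2])
  img[ri, ci, drop = FALSE]
}

#' Load an image/mask pair at the model input size
#'
#' The image is rescaled with a Lanczos filter to
#' `target_size x target_size` and clipped to \[0, 1\]; the mask is collapsed
#' to a single channel, resampled with nearest-neighbour (Lanczos ringing
#' would create non-binary values), and binarized at the 8-bit midpoint
#' (`> 127/255`).
#'
#' @param image_path,mask_path file paths.
#' @param target_size output side in pixels.
#' @return a `sample_pair` list: `image` (target, target, 3) in \[0, 1\],
#'   `mask` (target, target) binary, and `id` (the image file stem).
#' @export
load_pair <- function(image_path, mask_path, target_size = 352L) {
  img <- to_rgb(read_image(image_path))
  msk <- collapse_gray(read_image(mask_path))
  if (!identical(dim(img)[1:2], dim(msk)[1:2])) {
    warning(sprintf("image (%s) and mask (%s) sizes differ for %s; resizing both",
                    paste(dim(img)[1:2], collapse = "x"),
                    paste(dim(msk)[1:2], collapse = "x"), image_path))
  }
  img <- resize_lanczos(img, target_size, target_size)
  img[img < 0] <- 0
  img[img > 1] <- 1
  msk <- resize_nearest(msk, target_size, target_size)
  msk <- (msk > 127 / 255) * 1
  list(image = img, mask = msk,
       id = tools::file_path_sans_ext(basename(image_path)))
}

#' List paired images and masks in a dataset directory
#'
#' Expects the `images/` + `masks/` layout with files matched by identical
#' stem.
#'
#' @param data_dir dataset root.
#' @return data.frame with id, image, mask paths.
#' @export
list_pairs <- function(data_dir) {
  img_dir <- file.path(data_dir, "images")
  msk_dir <- file.path(data_dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop("expected images/ and masks/ under ", data_dir)
  }
  imgs <- list.files(img_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  stems <- tools::file_path_sans_ext(imgs)
  msks <- list.files(msk_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  msk_stems <- tools::file_path_sans_ext(msks)
  keep <- stems %in% msk_stems
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " image(s) without a matching mask")
  }
  ord <- order(stems[keep])
  data.frame(id = stems[keep][ord],
             image = file.path(img_dir, imgs[keep][ord]),
             mask = file.path(msk_dir, msks[match(stems[keep], msk_stems)][ord]),
             stringsAsFactors = FALSE)
}

#' Load every pair of a dataset directory
#'
#' @param data_dir dataset root (images/ + masks/).
#' @param target_size side length passed to [load_pair()].
#' @return list of `sample_pair`s.
#' @export
load_dataset <- function(data_dir, target_size = 352L) {
  pairs <- list_pairs(data_dir)
  lapply(seq_len(nrow(pairs)), function(i) {
    load_pair(pairs$image[i], pairs$mask[i], target_size)
  })
}

#' Split specification
#'
#' @param train_fraction,val_fraction,test_fraction fractions summing to 1
#'   (default 0.8 / 0.1 / 0.1).
#' @param seed permutation seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.8, val_fraction = 0.1,
                       test_fraction = 0.1, seed = 1L) {
  if (abs(train_fraction + val_fraction + test_fraction - 1) > 1e-9) {
    stop("split fractions must sum to 1")
  }
  structure(list(train_fraction = train_fraction, val_fraction = val_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Random train/validation/test split of ids
#'
#' Sizes are `floor(train * n)` and `floor(val * n)`, with the remainder
#' assigned to test, so the partition is always exhaustive and disjoint; the
#' permutation is fully determined by the seed.
#'
#' @param ids character vector of unique ids.
#' @param spec a [split_spec()].
#' @return list with `train`, `val`, `test` id vectors.
#' @export
split_dataset <- function(ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(ids)
  if (n < 3L) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  perm <- with_seed(spec$seed, sample(n))
  n_train <- floor(spec$train_fraction * n)
  n_val <- floor(spec$val_fraction * n)
  list(train = ids[perm[seq_len(n_train)]],
       val = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[(n_train + n_val + 1L):n]])
}

#' Write / read split manifests
#'
#' Plain-text id lists, one id per line, as `train.txt`, `val.txt`,
#' `test.txt` under `dir`.
#'
#' @param split a [split_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `write_split` returns `dir` invisibly; `read_split` the split list.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("train", "val", "test")) {
    writeLines(split[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  out <- lapply(c(train = "train", val = "val", test = "test"), function(nm) {
    f <- file.path(dir, paste0(nm, ".txt"))
    if (!file.exists(f)) stop("missing manifest: ", f)
    readLines(f)
  })
  out
}

#' Save a mask or probability map as an 8-bit PNG
#'
#' @param mask matrix with values in \[0, 1\].
#' @param path output PNG path.
#' @param threshold if non-`NULL`, binarize first (values >= threshold map
#'   to 255, the rest to 0).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, threshold = NULL) {
  if (any(mask < 0 | mask > 1)) stop("mask values must lie in [0, 1]")
  if (!is.null(threshold)) mask <- (mask >= threshold) * 1
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Save an RGB image as PNG
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}
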