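# ---------------------------------------------------------------------------
# Synthetic colonoscopy-like data: smoothly textured pinkish frames with a
# radial illumination vignette, containing 1-3 irregular bright blobs
# ("polyps") drawn as radially perturbed ellipses whose exact indicator is
# the ground-truth mask. Everything is generated at target resolution, so
# masks carry no resampling error, and a fixed seed reproduces a dataset
# bit-exactly.
# ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' @param n_samples number of image/mask pairs.
#' @param size square image side, divisible by 32.
#' @param blobs_range inclusive integer range of blobs per image (default 1-3).
#' @param radius_range blob base radius as a fraction of the side
#'   (default \[0.08, 0.35\]).
#' @param texture_noise_sd standard deviation of the background/foreground
#'   texture and sensor noise (default 0.05).
#' @param contrast_gap mean intensity offset of blob over background
#'   (default 0.35); 0 makes the foreground statistically indistinguishable
#'   when `texture_noise_sd` is also 0.
#' @param seed RNG seed; the dataset is fully determined by it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples = 200L, size = 64L, blobs_range = c(1L, 3L),
                         radius_range = c(0.08, 0.35), texture_noise_sd = 0.05,
                         contrast_gap = 0.35, seed = 1L) {
  size <- as.integer(size)
  if (size %% 32L != 0L) stop("`size` must be divisible by 32")
  if (radius_range[1] <= 0 || radius_range[2] >= 0.5 ||
      diff(radius_range) < 0) {
    stop("`radius_range` must lie within (0, 0.5)")
  }
  if (contrast_gap < 0) stop("`contrast_gap` must be >= 0")
  if (blobs_range[1] < 1L || blobs_range[2] < blobs_range[1]) {
    stop("invalid `blobs_range`")
  }
  # a blob's maximal extent is base radius * widest axis (the boundary
  # perturbation only shrinks rho below 1); its centre must fit inside the
  # frame with that margin.
  if (radius_range[2] * BLOB_AXIS_MAX >= 0.5) {
    stop("`radius_range` too large: blobs cannot fit inside the frame")
  }
  if (size * (1 - 2 * radius_range[2] * BLOB_AXIS_MAX) <= 2) {
    stop("`radius_range` too large for `size`: no room to place blob centres")
  }
  structure(list(n_samples = as.integer(n_samples), size = size,
                 blobs_range = as.integer(blobs_range),
                 radius_range = radius_range,
                 texture_noise_sd = texture_noise_sd,
                 contrast_gap = contrast_gap, seed = as.integer(seed)),
            class = "synth_config")
}

# shape constants of the perturbed-ellipse blob model
BLOB_AXIS_MIN <- 0.7
BLOB_AXIS_MAX <- 1.3
BLOB_AMP_MAX <- 0.25      # total radial perturbation amplitude
BLOB_HARMONICS <- 3:7     # low-order harmonics of the boundary

# smoothed unit-variance noise field (separable Gaussian blur of white noise)
smooth_noise <- function(size, sigma) {
  z <- matrix(stats::rnorm(size * size), size, size)
  idx <- seq_len(size)
  B <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  B <- B / rowSums(B)
  s <- B %*% z %*% t(B)
  s / stats::sd(s)
}

# One perturbed-ellipse blob mask; geometry drawn from the current RNG.
# The radial profile is rho(theta) = (1 - A) + sum_k a_k cos(k theta + phi_k)
# with A = sum_k a_k <= BLOB_AMP_MAX, so rho <= 1 always: the base radius is
# a hard bound on the blob extent and the enclosed area is
# pi a b ((1 - A)^2 + sum a_k^2 / 2) exactly (harmonic orthogonality).
draw_blob <- function(size, radius_range) {
  r <- stats::runif(1, radius_range[1], radius_range[2]) * size
  ax <- stats::runif(2, BLOB_AXIS_MIN, BLOB_AXIS_MAX)
  phi <- stats::runif(1, 0, 2 * pi)
  n_h <- length(BLOB_HARMONICS)
  amps <- stats::runif(n_h)
  amps <- amps / sum(amps) * stats::runif(1, 0.05, BLOB_AMP_MAX)
  phases <- stats::runif(n_h, 0, 2 * pi)
  margin <- r * BLOB_AXIS_MAX
  cx <- stats::runif(1, margin + 1, size - margin)
  cy <- stats::runif(1, margin + 1, size - margin)

  xs <- matrix(rep(seq_len(size), each = size), size) - cx
  ys <- matrix(rep(seq_len(size), times = size), size) - cy
  u <- (cos(phi) * xs + sin(phi) * ys) / (r * ax[1])
  v <- (-sin(phi) * xs + cos(phi) * ys) / (r * ax[2])
  re <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  A <- sum(amps)
  rho <- matrix(1 - A, size, size)
  for (k in seq_len(n_h)) {
    rho <- rho + amps[k] * cos(BLOB_HARMONICS[k] * th + phases[k])
  }
  list(mask = (re <= rho) * 1,
       area = pi * r^2 * ax[1] * ax[2] * ((1 - A)^2 + sum(amps^2) / 2))
}

generate_sample <- function(config, id) {
  s <- config$size
  sd_t <- config$texture_noise_sd
  bg <- 0.5 + 0.08 * smooth_noise(s, sigma = s / 8)
  idx <- seq_len(s)
  r2 <- outer((idx - (s + 1) / 2)^2, (idx - (s + 1) / 2)^2, "+")
  vignette <- 1 - 0.35 * r2 / max(r2)
  base <- bg * vignette

  n_blobs <- sample(seq(config$blobs_range[1], config$blobs_range[2]), 1)
  mask <- matrix(0, s, s)
  for (b in seq_len(n_blobs)) {
    mask <- pmax(mask, draw_blob(s, config$radius_range)$mask)
  }
  fg_texture <- smooth_noise(s, sigma = s / 16)
  gray <- base + (config$contrast_gap + sd_t * fg_texture) * mask

  tint_bg <- c(1.00, 0.72, 0.68)   # endoscopic pink
  tint_fg <- c(1.00, 0.80, 0.55)   # polyp offset paler/yellowish
  img <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    # the foreground tint rides on the contrast gap so that a zero gap with
    # zero texture noise leaves the blob statistically invisible
    img[, , ch] <- gray * tint_bg[ch] +
      config$contrast_gap * (tint_fg[ch] - tint_bg[ch]) * mask +
      sd_t * matrix(stats::rnorm(s * s), s, s)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask, id = id)
}

#' Generate a synthetic segmentation dataset
#'
#' @param config a [synth_config()].
#' @return list of sample pairs (`image`, `mask`, `id`), bit-reproducible
#'   for a fixed seed.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_samples = 2, size = 64, seed = 7))
#' range(ds[[1]]$image); sort(unique(as.vector(ds[[1]]$mask)))
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_samples), function(i) {
      generate_sample(config, sprintf("synth_%04d", i))
    })
  })
}

#' Analytic bounds on the foreground fraction
#'
#' Hard bounds implied by the blob model: every blob is a perturbed ellipse
#' with base radius in `radius_range`, axis factors in \[0.7, 1.3\], and a
#' radial profile bounded in \[1 - 2 * 0.25, 1\], fully contained in the
#' frame. The union of k blobs is bounded below by one smallest blob and
#' above by k largest blobs.
#'
#' @param config a [synth_config()].
#' @return c(lower, upper) bounds on the per-image foreground fraction.
#' @export
foreground_fraction_bounds <- function(config) {
  lo_area <- pi * (config$radius_range[1] * BLOB_AXIS_MIN)^2 *
    (1 - 2 * BLOB_AMP_MAX)^2
  hi_area <- pi * (config$radius_range[2] * BLOB_AXIS_MAX)^2
  c(lower = lo_area, upper = min(1, config$blobs_range[2] * hi_area))
}

#' Generate datasets along a contrast-difficulty sweep
#'
#' Produces datasets identical in blob geometry, texture and noise (same
#' seed) that differ only in `contrast_gap`, emulating the hard case of
#' polyps whose colours blend into the background.
#'
#' @param base a [synth_config()].
#' @param gaps numeric vector of contrast gaps, sorted descending
#'   (easiest first).
#' @return named list of datasets, one per gap.
#' @export
difficulty_sweep <- function(base, gaps) {
  stopifnot(inherits(base, "synth_config"))
  if (is.unsorted(rev(gaps))) stop("`gaps` must be sorted descending")
  out <- lapply(gaps, function(g) {
    cfg <- base
    cfg$contrast_gap <- g
    generate_dataset(cfg)
  })
  names(out) <- sprintf("gap_%g", gaps)
  out
}

#' Write a dataset to the images/ + masks/ layout
#'
#' @param samples list of sample pairs.
#' @param dir output root; `images/` and `masks/` are created below it.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    save_image(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    save_mask(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  invisible(dir)
}
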