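# ---------------------------------------------------------------------------
# Training-time augmentation: horizontal/vertical flips, colour jitter
# (image only), and affine transforms applied with identical sampled
# parameters to the image and its segmentation mask.
#
# Printed policy: brightness factor U[0.6, 1.6], contrast 0.2, saturation
# 0.1, hue 0.01, rotation U[-180, 180] deg, translations U[-0.125, 0.125]
# per axis, scale U[0.5, 1.5], shear U[-22.5, 22.5] deg (the asymmetric
# variant [-22.5, 22] is available via `shear_symmetric = FALSE`).
# ---------------------------------------------------------------------------

#' Augmentation configuration
#'
#' Defaults are the exact published policy values. Contrast, saturation and
#' hue follow the torchvision/Albumentations colour-jitter convention: a
#' factor `f` means a multiplier drawn uniformly from `[1 - f, 1 + f]` (for
#' hue, a shift from `[-f, f]` of the hue circle).
#'
#' @param p_hflip,p_vflip flip probabilities.
#' @param brightness_range multiplicative brightness interval.
#' @param contrast,saturation,hue jitter factors.
#' @param rotation_range rotation interval in degrees.
#' @param translate_range per-axis translation interval, fraction of the side.
#' @param scale_range scaling interval.
#' @param shear_range shear interval in degrees.
#' @param shear_symmetric if `FALSE`, use the asymmetric printed interval
#'   `[-22.5, 22]` instead of the symmetric default.
#' @return an `augment_config` list.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5,
                           brightness_range = c(0.6, 1.6), contrast = 0.2,
                           saturation = 0.1, hue = 0.01,
                           rotation_range = c(-180, 180),
                           translate_range = c(-0.125, 0.125),
                           scale_range = c(0.5, 1.5),
                           shear_range = c(-22.5, 22.5),
                           shear_symmetric = TRUE) {
  if (!shear_symmetric) shear_range <- c(-22.5, 22)
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            length(brightness_range) == 2, diff(brightness_range) >= 0,
            contrast >= 0, saturation >= 0, hue >= 0, hue <= 0.5,
            diff(rotation_range) >= 0, diff(translate_range) >= 0,
            diff(scale_range) >= 0, scale_range[1] > 0,
            diff(shear_range) >= 0)
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 brightness_range = brightness_range, contrast = contrast,
                 saturation = saturation, hue = hue,
                 rotation_range = rotation_range,
                 translate_range = translate_range, scale_range = scale_range,
                 shear_range = shear_range),
            class = "augment_config")
}

#' Identity augmentation configuration
#'
#' All probabilities zero and all intervals collapsed to identity values;
#' `augment_pair` returns its inputs unchanged under this configuration.
#'
#' @return an `augment_config`.
#' @export
augment_config_identity <- function() {
  augment_config(p_hflip = 0, p_vflip = 0, brightness_range = c(1, 1),
                 contrast = 0, saturation = 0, hue = 0,
                 rotation_range = c(0, 0), translate_range = c(0, 0),
                 scale_range = c(1, 1), shear_range = c(0, 0))
}

#' Sample one augmentation parameter record
#'
#' Draws every transform parameter uniformly over its configured interval
#' from R's RNG stream. The record suffices to replay the transform exactly
#' via `augment_pair(..., params = record)`.
#'
#' @param config an [augment_config()].
#' @return named list of sampled parameters.
#' @export
sample_params <- function(config) {
  stopifnot(inherits(config, "augment_config"))
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  list(
    hflip = stats::runif(1) < config$p_hflip,
    vflip = stats::runif(1) < config$p_vflip,
    brightness = runif1(config$brightness_range),
    contrast = runif1(c(max(0, 1 - config$contrast), 1 + config$contrast)),
    saturation = runif1(c(max(0, 1 - config$saturation), 1 + config$saturation)),
    hue = runif1(c(-config$hue, config$hue)),
    rotation = runif1(config$rotation_range),
    translate_x = runif1(config$translate_range),
    translate_y = runif1(config$translate_range),
    scale = runif1(config$scale_range),
    shear = runif1(config$shear_range)
  )
}

#' Augment an image/mask pair
#'
#' Geometric transforms (flips, then one affine combining rotation,
#' translation, scale and shear about the image centre) are applied with the
#' same sampled parameters to image and mask; colour jitter is applied to the
#' image only. The image is resampled bilinearly with reflection padding and
#' clipped to \[0, 1\]; the mask with nearest-neighbour, zero fill, and
#' re-binarized.
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param mask (H, W) binary matrix of the same spatial size.
#' @param config an [augment_config()].
#' @param params optional parameter record from [sample_params()] to replay;
#'   if `NULL`, parameters are drawn from the current RNG stream.
#' @param seed optional seed (leaves the caller's RNG untouched).
#' @return list with `image`, `mask`, and the `params` used.
#' @export
augment_pair <- function(image, mask, config = augment_config(),
                         params = NULL, seed = NULL) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be (H, W, 3)")
  if (!identical(dim(mask), d[1:2])) {
    stop("image and mask spatial sizes differ")
  }
  if (is.null(params)) {
    params <- if (is.null(seed)) sample_params(config)
              else with_seed(seed, sample_params(config))
  }
  p <- params
  if (p$hflip) {
    image <- image[, rev(seq_len(d[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(d[2])), drop = FALSE]
  }
  if (p$vflip) {
    image <- image[rev(seq_len(d[1])), , , drop = FALSE]
    mask <- mask[rev(seq_len(d[1])), , drop = FALSE]
  }
  identity_affine <- p$rotation == 0 && p$translate_x == 0 &&
    p$translate_y == 0 && p$scale == 1 && p$shear == 0
  if (!identity_affine) {
    inv <- affine_inverse(d[1], d[2], p)
    image <- warp_bilinear(image, inv)
    mask <- warp_nearest(mask, inv)
  }
  image <- color_jitter(image, p)
  image[image < 0] <- 0
  image[image > 1] <- 1
  mask <- (mask > 0.5) * 1
  list(image = image, mask = mask, params = params)
}

# inverse affine map from output pixel-centre coords to input coords;
# forward map: translate(center + t*size) . rotate . shear . scale . translate(-center)
affine_inverse <- function(H, W, p) {
  th <- p$rotation * pi / 180
  sh <- tan(p$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  A <- (R %*% S) * p$scale
  cx <- (W + 1) / 2
  cy <- (H + 1) / 2
  off <- c(cx + p$translate_x * W, cy + p$translate_y * H)
  Ainv <- solve(A)
  # x_in = Ainv %*% (x_out - off) + center
  list(Ainv = Ainv, off = off, center = c(cx, cy))
}

# output-grid input coordinates for an inverse affine map
grid_coords <- function(H, W, inv) {
  xo <- rep(seq_len(W), each = H)
  yo <- rep(seq_len(H), times = W)
  dx <- xo - inv$off[1]
  dy <- yo - inv$off[2]
  xi <- inv$Ainv[1, 1] * dx + inv$Ainv[1, 2] * dy + inv$center[1]
  yi <- inv$Ainv[2, 1] * dx + inv$Ainv[2, 2] * dy + inv$center[2]
  list(x = xi, y = yi)
}

reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j < 0, j + 2 * n, j)
  ifelse(j >= n, 2 * n - 1 - j, j) + 1
}

warp_bilinear <- function(image, inv) {
  d <- dim(image)
  g <- grid_coords(d[1], d[2], inv)
  x0 <- floor(g$x); y0 <- floor(g$y)
  fx <- g$x - x0; fy <- g$y - y0
  x0r <- reflect_index(x0, d[2]); x1r <- reflect_index(x0 + 1, d[2])
  y0r <- reflect_index(y0, d[1]); y1r <- reflect_index(y0 + 1, d[1])
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    m <- image[, , ch]
    v <- (1 - fx) * ((1 - fy) * m[cbind(y0r, x0r)] + fy * m[cbind(y1r, x0r)]) +
      fx * ((1 - fy) * m[cbind(y0r, x1r)] + fy * m[cbind(y1r, x1r)])
    out[, , ch] <- matrix(v, d[1], d[2])
  }
  out
}

warp_nearest <- function(mask, inv) {
  d <- dim(mask)
  g <- grid_coords(d[1], d[2], inv)
  xi <- round(g$x); yi <- round(g$y)
  ok <- xi >= 1 & xi <= d[2] & yi >= 1 & yi <= d[1]
  v <- numeric(length(xi))
  v[ok] <- mask[cbind(yi[ok], xi[ok])]
  matrix(v, d[1], d[2])
}

color_jitter <- function(image, p) {
  if (p$brightness != 1) image <- image * p$brightness
  if (p$contrast != 1) {
    gray_mean <- mean(luminance(image))
    image <- gray_mean + (image - gray_mean) * p$contrast
  }
  if (p$saturation != 1) {
    g <- luminance(image)
    for (ch in 1:3) image[, , ch] <- g + (image[, , ch] - g) * p$saturation
  }
  if (p$hue != 0) image <- shift_hue(image, p$hue)
  image
}

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# hue shift as a fraction of the hue circle, via RGB <-> HSV
shift_hue <- function(image, dh) {
  d <- dim(image)
  rgb <- rbind(as.vector(pmin(pmax(image[, , 1], 0), 1)),
               as.vector(pmin(pmax(image[, , 2], 0), 1)),
               as.vector(pmin(pmax(image[, , 3], 0), 1)))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- (hsv[1, ] + dh) %% 1
  out <- hsv2rgb(h, hsv[2, ], hsv[3, ])
  array(c(out[1, ], out[2, ], out[3, ]), d)
}

hsv2rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}
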