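# ---------------------------------------------------------------------------
# The DUCK block and its constituent block types.
#
# Simulated kernel sizes (receptive-field side lengths) by construction:
#   residual chain of 1 / 2 / 3 blocks      ->  5 / 9 / 13
#   midscope  (3x3 convs, dilations 1, 2)   ->  7
#   widescope (3x3 convs, dilations 1,2,4)  -> 15
#   separated (1xN then Nx1, default N=13)  ->  N
# The dilation schedules are the minimal-depth solutions of
# 1 + sum_i 2*d_i = target for the targets 7 and 15.
# ---------------------------------------------------------------------------

BLOCK_KINDS <- c("residual", "midscope", "widescope", "separated",
                 "duck", "simple_conv", "strided_downsample")

check_filters <- function(filters) {
  if (length(filters) != 1L || !is.finite(filters) || filters < 1 ||
      filters != as.integer(filters)) {
    stop("`filters` must be a positive integer")
  }
  as.integer(filters)
}

nn_residual <- function(in_ch, filters, norm = "batch", init = "he") {
  c1 <- nn_conv2d(in_ch, filters, init = init)
  c2 <- nn_conv2d(filters, filters, init = init)
  shortcut <- if (in_ch == filters) nn_identity() else
    nn_conv2d(in_ch, filters, kh = 1L, kw = 1L, activation = "linear", init = init)
  bn <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    main <- c2$forward(c1$forward(x, training), training)
    sc <- shortcut$forward(x, training)
    bn$forward(ag_add2(main, sc), training)
  }
  nn_module(forward, modules = list(conv1 = c1, conv2 = c2,
                                    shortcut = shortcut, bn = bn),
            kind = "residual")
}

nn_residual_chain <- function(in_ch, filters, repeats, norm = "batch",
                              init = "he") {
  if (!repeats %in% 1:3) stop("`repeats` must be 1, 2, or 3")
  blocks <- list()
  ch <- in_ch
  for (i in seq_len(repeats)) {
    blocks[[paste0("res", i)]] <- nn_residual(ch, filters, norm, init)
    ch <- filters
  }
  forward <- function(x, training = FALSE) {
    for (b in blocks) x <- b$forward(x, training)
    x
  }
  nn_module(forward, modules = blocks, kind = "residual_chain")
}

nn_midscope <- function(in_ch, filters, norm = "batch", init = "he") {
  c1 <- nn_conv2d(in_ch, filters, dilation = 1L, init = init)
  c2 <- nn_conv2d(filters, filters, dilation = 2L, init = init)
  bn <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    bn$forward(c2$forward(c1$forward(x, training), training), training)
  }
  nn_module(forward, modules = list(conv1 = c1, conv2 = c2, bn = bn),
            kind = "midscope")
}

nn_widescope <- function(in_ch, filters, norm = "batch", init = "he") {
  c1 <- nn_conv2d(in_ch, filters, dilation = 1L, init = init)
  c2 <- nn_conv2d(filters, filters, dilation = 2L, init = init)
  c3 <- nn_conv2d(filters, filters, dilation = 4L, init = init)
  bn <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    bn$forward(
      c3$forward(c2$forward(c1$forward(x, training), training), training),
      training)
  }
  nn_module(forward, modules = list(conv1 = c1, conv2 = c2, conv3 = c3, bn = bn),
            kind = "widescope")
}

nn_separated <- function(in_ch, filters, n = 13L, norm = "batch", init = "he") {
  if (n %% 2L == 0L || n < 3L) {
    stop("`n` must be an odd integer >= 3 (symmetric same-padding)")
  }
  c1 <- nn_conv2d(in_ch, filters, kh = 1L, kw = n, init = init)
  c2 <- nn_conv2d(filters, filters, kh = n, kw = 1L, init = init)
  bn <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    bn$forward(c2$forward(c1$forward(x, training), training), training)
  }
  nn_module(forward, modules = list(conv1 = c1, conv2 = c2, bn = bn),
            kind = "separated")
}

# Six parallel branches merged by elementwise addition, with normalization
# before branching and after the sum.
nn_duck <- function(in_ch, filters, norm = "batch", separated_n = 13L,
                    init = "he") {
  bn_in <- nn_norm(in_ch, norm)
  branches <- list(
    widescope = nn_widescope(in_ch, filters, norm, init),
    midscope = nn_midscope(in_ch, filters, norm, init),
    res1 = nn_residual_chain(in_ch, filters, 1L, norm, init),
    res2 = nn_residual_chain(in_ch, filters, 2L, norm, init),
    res3 = nn_residual_chain(in_ch, filters, 3L, norm, init),
    separated = nn_separated(in_ch, filters, separated_n, norm, init)
  )
  bn_out <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    x <- bn_in$forward(x, training)
    outs <- lapply(branches, function(b) b$forward(x, training))
    bn_out$forward(ag_add_n(outs), training)
  }
  nn_module(forward,
            modules = c(list(bn_in = bn_in), branches, list(bn_out = bn_out)),
            kind = "duck")
}

# Classic U-Net stage (two 3x3 conv+ReLU) used by the ablation variant.
nn_simple_conv <- function(in_ch, filters, norm = "batch", init = "he") {
  c1 <- nn_conv2d(in_ch, filters, init = init)
  c2 <- nn_conv2d(filters, filters, init = init)
  bn <- nn_norm(filters, norm)
  forward <- function(x, training = FALSE) {
    bn$forward(c2$forward(c1$forward(x, training), training), training)
  }
  nn_module(forward, modules = list(conv1 = c1, conv2 = c2, bn = bn),
            kind = "simple_conv")
}

# 2x2 convolution with stride 2 (the learned downscaling unit).
nn_strided_downsample <- function(in_ch, filters, init = "he") {
  conv <- nn_conv2d(in_ch, filters, kh = 2L, kw = 2L, stride = 2L,
                    activation = "linear", init = init, pad = c(0L, 0L))
  nn_module(function(x, training = FALSE) conv$forward(x, training),
            modules = list(conv = conv), kind = "strided_downsample")
}

new_block <- function(kind, in_ch, filters, norm = "batch",
                      separated_n = 13L, repeats = 1L, init = "he") {
  kind <- match.arg(kind, BLOCK_KINDS)
  filters <- check_filters(filters)
  switch(kind,
    residual = nn_residual_chain(in_ch, filters, repeats, norm, init),
    midscope = nn_midscope(in_ch, filters, norm, init),
    widescope = nn_widescope(in_ch, filters, norm, init),
    separated = nn_separated(in_ch, filters, separated_n, norm, init),
    duck = nn_duck(in_ch, filters, norm, separated_n, init),
    simple_conv = nn_simple_conv(in_ch, filters, norm, init),
    strided_downsample = nn_strided_downsample(in_ch, filters, init))
}

# ---- functional interface on plain (H, W, C) arrays -----------------------

check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || any(dim(x) < 1L)) {
    stop("feature map must be a (H, W, C) array with positive dimensions")
  }
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  invisible(x)
}

apply_block <- function(kind, x, filters, norm = "batch", seed = NULL, ...) {
  check_feature_map(x)
  mod <- with_seed(seed, new_block(kind, in_ch = dim(x)[3], filters = filters,
                                   norm = norm, ...))
  xin <- ag_const(array(x, dim = c(dim(x), 1L)))
  y <- mod$forward(xin, training = FALSE)$value
  array(y, dim = dim(y)[1:3])
}

#' Apply a residual block
#'
#' Two 3x3 same-padded convolutions with ReLU plus an additive shortcut
#' (a 1x1 convolution when the channel counts differ). A single block has a
#' 5x5 receptive field; see [residual_chain()] for 9x9 and 13x13.
#'
#' @param x feature map, an (H, W, C) array.
#' @param filters number of output channels.
#' @param norm `"batch"` (default) or `"none"`.
#' @param seed optional seed for the weight initialization.
#' @return an (H, W, `filters`) array.
#' @export
#' @examples
#' y <- residual_block(array(rnorm(8 * 8 * 2), c(8, 8, 2)), filters = 4, seed = 1)
#' dim(y)
residual_block <- function(x, filters, norm = "batch", seed = NULL) {
  apply_block("residual", x, filters, norm, seed, repeats = 1L)
}

#' Apply a chain of 1-3 residual blocks
#'
#' Chains of one, two, and three residual blocks simulate kernel sizes of
#' 5x5, 9x9, and 13x13 respectively.
#'
#' @inheritParams residual_block
#' @param repeats chain length, one of 1, 2, 3.
#' @return an (H, W, `filters`) array.
#' @export
residual_chain <- function(x, filters, repeats, norm = "batch", seed = NULL) {
  if (length(repeats) != 1L || !repeats %in% 1:3) {
    stop("`repeats` must be 1, 2, or 3")
  }
  apply_block("residual", x, filters, norm, seed, repeats = as.integer(repeats))
}

#' Apply a midscope block (simulated 7x7 kernel)
#'
#' Two 3x3 same-padded convolutions with dilation rates 1 then 2, spreading
#' nine kernel taps over a 7x7 area with far fewer parameters than a dense
#' 7x7 convolution.
#'
#' @inheritParams residual_block
#' @return an (H, W, `filters`) array.
#' @export
midscope_block <- function(x, filters, norm = "batch", seed = NULL) {
  apply_block("midscope", x, filters, norm, seed)
}

#' Apply a widescope block (simulated 15x15 kernel)
#'
#' Three 3x3 same-padded convolutions with dilation rates 1, 2, 4.
#'
#' @inheritParams residual_block
#' @return an (H, W, `filters`) array.
#' @export
widescope_block <- function(x, filters, norm = "batch", seed = NULL) {
  apply_block("widescope", x, filters, norm, seed)
}

#' Apply a separated block (spatially factorized NxN kernel)
#'
#' A 1xN convolution followed by an NxN one simulates an NxN kernel at a
#' fraction of the parameters, at the cost of the rank-1 ("loss of
#' diagonality") restriction on the simulated kernel.
#'
#' @inheritParams residual_block
#' @param n simulated kernel side; odd integer >= 3 (default 13).
#' @return an (H, W, `filters`) array.
#' @export
separated_block <- function(x, filters, n = 13L, norm = "batch", seed = NULL) {
  apply_block("separated", x, filters, norm, seed, separated_n = as.integer(n))
}

#' Apply a DUCK block
#'
#' Six parallel branches — widescope, midscope, chains of one, two and three
#' residual blocks, and a separated block — each mapping the input to
#' `filters` channels, combined by elementwise addition, with batch-style
#' normalization before branching and after the sum.
#'
#' @inheritParams separated_block
#' @return an (H, W, `filters`) array.
#' @export
duck_block <- function(x, filters, n = 13L, norm = "batch", seed = NULL) {
  apply_block("duck", x, filters, norm, seed, separated_n = as.integer(n))
}

#' Apply a simple convolution block (ablation baseline)
#'
#' The classic U-Net stage: two 3x3 same-padded convolutions with ReLU. A
#' drop-in replacement for [duck_block()] with identical output shapes.
#'
#' @inheritParams residual_block
#' @return an (H, W, `filters`) array.
#' @export
simple_conv_block <- function(x, filters, norm = "batch", seed = NULL) {
  apply_block("simple_conv", x, filters, norm, seed)
}

#' Downscale a feature map with a 2x2 stride-2 convolution
#'
#' @inheritParams residual_block
#' @return an (H/2, W/2, `filters`) array; errors on odd spatial dimensions.
#' @export
strided_downsample <- function(x, filters, seed = NULL) {
  check_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("strided_downsample requires even spatial dimensions, got ",
         d[1], "x", d[2])
  }
  apply_block("strided_downsample", x, filters, seed = seed)
}

# ---- receptive-field oracle ------------------------------------------------

#' Block specification
#'
#' A light record describing one block type, consumed by
#' [measure_receptive_field()].
#'
#' @param kind one of `"residual"`, `"midscope"`, `"widescope"`,
#'   `"separated"`, `"duck"`, `"simple_conv"`, `"strided_downsample"`.
#' @param filters output channels (>= 1).
#' @param repeats residual chain length in 1..3 (residual only).
#' @param separated_n odd simulated kernel side (separated/duck).
#' @return a `block_spec` list.
#' @export
block_spec <- function(kind, filters = 1L, repeats = 1L, separated_n = 13L) {
  kind <- match.arg(kind, BLOCK_KINDS)
  filters <- check_filters(filters)
  if (!repeats %in% 1:3) stop("`repeats` must be 1, 2, or 3")
  if (separated_n %% 2L == 0L || separated_n < 3L) {
    stop("`separated_n` must be an odd integer >= 3")
  }
  structure(list(kind = kind, filters = filters, repeats = as.integer(repeats),
                 separated_n = as.integer(separated_n)),
            class = "block_spec")
}

#' Measure a block's receptive field by its gradient footprint
#'
#' Instantiates the block with strictly positive weights, no normalization and
#' a single input channel on a `probe_size` x `probe_size` probe,
#' backpropagates from the central output unit, and returns the side lengths
#' of the bounding box of input positions with nonzero gradient. Positive
#' weights guarantee that contributions cannot cancel, so the footprint
#' equals the architectural receptive field exactly.
#'
#' @param block a `block_spec`, a kind string, or an `nn_module`.
#' @param probe_size odd probe side, strictly larger than the expected span.
#' @param seed seed for the (positive) weight draw; the result is weight-
#'   independent by construction but deterministic for a fixed seed.
#' @return integer vector `c(height_span, width_span)`; errors if the
#'   footprint saturates the probe (caller must enlarge `probe_size`).
#' @export
#' @examples
#' measure_receptive_field("midscope", probe_size = 31)  # 7 7
measure_receptive_field <- function(block, probe_size = 41L, seed = 1L) {
  if (is.character(block)) block <- block_spec(block)
  if (inherits(block, "block_spec")) {
    mod <- with_seed(seed, new_block(block$kind, in_ch = 1L,
                                     filters = block$filters, norm = "none",
                                     separated_n = block$separated_n,
                                     repeats = block$repeats,
                                     init = "positive"))
  } else if (inherits(block, "nn_module")) {
    mod <- block
  } else {
    stop("`block` must be a block_spec, a kind string, or an nn_module")
  }
  p <- as.integer(probe_size)
  if (p < 3L || p %% 2L == 0L) stop("`probe_size` must be an odd integer >= 3")
  xin <- ag_const(array(1, dim = c(p, p, 1L, 1L)))
  out <- mod$forward(xin, training = FALSE)
  od <- dim(out$value)
  seed_grad <- array(0, od)
  ctr <- (od[1:2] + 1L) %/% 2L
  seed_grad[ctr[1], ctr[2], 1L, 1L] <- 1
  ag_backward(out, seed = seed_grad)
  g <- xin$grad
  hit <- apply(abs(g) > 1e-12, c(1, 2), any)
  rows <- which(rowSums(hit) > 0)
  cols <- which(colSums(hit) > 0)
  if (length(rows) == 0L) stop("no gradient reached the input probe")
  if (min(rows) == 1L || max(rows) == p || min(cols) == 1L || max(cols) == p) {
    stop("receptive field saturates the probe; enlarge `probe_size`")
  }
  c(height_span = diff(range(rows)) + 1L, width_span = diff(range(cols)) + 1L)
}

#' Count the learnable parameters of a block kind
#'
#' @inheritParams block_spec
#' @param in_ch input channel count.
#' @param norm `"batch"` or `"none"`.
#' @return integer scalar.
#' @export
block_parameter_count <- function(kind, in_ch, filters, repeats = 1L,
                                  separated_n = 13L, norm = "batch") {
  mod <- with_seed(1L, new_block(kind, in_ch = in_ch, filters = filters,
                                 norm = norm, separated_n = separated_n,
                                 repeats = repeats))
  sum(vapply(nn_params(mod), function(p) length(p$value), numeric(1)))
}
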