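# ---------------------------------------------------------------------------
# DUCK-Net assembly: dual-path residual-downsampling encoder, four-residual
# bottleneck, nearest-neighbour-upsampled decoder with addition skips and
# halved filter counts, sigmoid head.
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' @param filters base filter count F; channels double at every downscale
#'   (F*2^i at level i). The reference sizes are 17 (small) and 34 (large).
#' @param input_size square input side in pixels; must be divisible by
#'   `2^depth`. Default 352.
#' @param depth number of 2x downscales (default 5; 352 -> 11 bottleneck).
#' @param block_type `"duck"` or, for the ablation baseline, `"simple_conv"`.
#' @param bottleneck_residual_blocks residual blocks at the coarsest
#'   resolution (default 4): the first half at width F*2^depth, the second
#'   half at F*2^(depth-1) so the first upsample matches the encoder.
#' @param seed integer seed for weight initialization.
#' @param norm `"batch"` (default) or `"none"`.
#' @param separated_n simulated kernel side of the separated branch.
#' @return a `model_config` list.
#' @export
model_config <- function(filters = 17L, input_size = 352L, depth = 5L,
                         block_type = c("duck", "simple_conv"),
                         bottleneck_residual_blocks = 4L, seed = 1L,
                         norm = "batch", separated_n = 13L) {
  block_type <- match.arg(block_type)
  filters <- check_filters(filters)
  depth <- as.integer(depth)
  input_size <- as.integer(input_size)
  if (depth < 1L) stop("`depth` must be >= 1")
  if (input_size %% (2L^depth) != 0L) {
    stop(sprintf("`input_size` (%d) must be divisible by 2^depth (%d)",
                 input_size, 2L^depth))
  }
  if (bottleneck_residual_blocks < 1L) {
    stop("`bottleneck_residual_blocks` must be >= 1")
  }
  structure(list(filters = filters, input_size = input_size, depth = depth,
                 block_type = block_type,
                 bottleneck_residual_blocks = as.integer(bottleneck_residual_blocks),
                 seed = as.integer(seed), norm = norm,
                 separated_n = as.integer(separated_n)),
            class = "model_config")
}

#' Encoder stage shapes implied by a configuration
#'
#' @param config a [model_config()].
#' @return data.frame with one row per encoder level: spatial side and the
#'   channel counts of the processing path and of the downsampling units.
#' @export
stage_shapes <- function(config) {
  i <- 0:config$depth
  data.frame(level = i,
             side = config$input_size %/% (2L^i),
             channels = config$filters * 2L^i)
}

#' Build a DUCK-Net model
#'
#' The encoder applies a block (`block_type`) at each resolution followed by a
#' 2x2 stride-2 convolution; a secondary downscaling path of pure stride-2
#' convolutions carries the raw input to every level and is merged into the
#' main path by elementwise addition. The coarsest level holds
#' `bottleneck_residual_blocks` residual blocks. The decoder upsamples 2x
#' (nearest neighbour), adds the encoder block output of that resolution, and
#' applies a block with half the filter count of the level below. A 1x1
#' convolution with a sigmoid produces the per-pixel foreground probability.
#'
#' @param config a [model_config()].
#' @return a `ducknet` object.
#' @export
build_ducknet <- function(config) {
  stopifnot(inherits(config, "model_config"))
  f <- config$filters
  depth <- config$depth
  nb <- config$bottleneck_residual_blocks
  norm <- config$norm
  mk_block <- function(in_ch, out_ch) {
    new_block(config$block_type, in_ch, out_ch, norm = norm,
              separated_n = config$separated_n)
  }
  modules <- with_seed(config$seed, {
    m <- list()
    for (i in seq_len(depth)) {
      m[[paste0("p_conv", i)]] <- nn_strided_downsample(
        if (i == 1L) 3L else f * 2L^(i - 1L), f * 2L^i)
    }
    m[["enc_block1"]] <- mk_block(3L, f)
    for (i in seq_len(depth - 1L)) {
      m[[paste0("down_conv", i)]] <- nn_strided_downsample(f * 2L^(i - 1L), f * 2L^i)
      m[[paste0("enc_block", i + 1L)]] <- mk_block(f * 2L^i, f * 2L^i)
    }
    m[[paste0("down_conv", depth)]] <- nn_strided_downsample(f * 2L^(depth - 1L),
                                                             f * 2L^depth)
    # bottleneck: first half at the deepest width, second half at half that
    n_deep <- ceiling(nb / 2)
    ch <- f * 2L^depth
    for (j in seq_len(nb)) {
      out_ch <- if (j <= n_deep) f * 2L^depth else f * 2L^(depth - 1L)
      m[[paste0("bottleneck", j)]] <- nn_residual(ch, out_ch, norm = norm)
      ch <- out_ch
    }
    for (i in depth:1L) {
      m[[paste0("dec_block", i)]] <- mk_block(f * 2L^(i - 1L),
                                              f * 2L^(max(i - 2L, 0L)))
    }
    m[["head"]] <- nn_conv2d(f, 1L, kh = 1L, kw = 1L, activation = "sigmoid")
    m
  })

  model <- list(config = config,
                module = nn_module(NULL, modules = modules, kind = "ducknet"))
  class(model) <- "ducknet"
  model
}

# Forward pass on a (S, S, 3, N) array; returns the sigmoid output node.
# When `trace` is an environment, records the encoder stage shapes seen live.
ducknet_forward <- function(model, x, training = FALSE, trace = NULL) {
  cfg <- model$config
  m <- model$module$modules
  depth <- cfg$depth
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != 3L) {
    stop(sprintf("expected input of shape (%d, %d, 3, N), got (%s); resize first",
                 cfg$input_size, cfg$input_size, paste(d, collapse = ", ")))
  }
  xin <- ag_const(x)
  ps <- vector("list", depth)
  p <- xin
  for (i in seq_len(depth)) {
    p <- m[[paste0("p_conv", i)]]$forward(p, training)
    ps[[i]] <- p
  }
  ts <- vector("list", depth)
  t <- m$enc_block1$forward(xin, training)
  ts[[1]] <- t
  if (!is.null(trace)) trace$stages <- list(dim(t$value))
  for (i in seq_len(depth - 1L)) {
    dn <- m[[paste0("down_conv", i)]]$forward(t, training)
    t <- m[[paste0("enc_block", i + 1L)]]$forward(ag_add2(dn, ps[[i]]), training)
    ts[[i + 1L]] <- t
    if (!is.null(trace)) trace$stages <- c(trace$stages, list(dim(t$value)))
  }
  b <- ag_add2(m[[paste0("down_conv", depth)]]$forward(t, training), ps[[depth]])
  if (!is.null(trace)) trace$stages <- c(trace$stages, list(dim(b$value)))
  for (j in seq_len(cfg$bottleneck_residual_blocks)) {
    b <- m[[paste0("bottleneck", j)]]$forward(b, training)
  }
  q <- b
  for (i in depth:1L) {
    u <- ag_add2(ag_upsample2x(q), ts[[i]])
    q <- m[[paste0("dec_block", i)]]$forward(u, training)
  }
  m$head$forward(q, training)
}

#' Predict segmentation probability maps
#'
#' @param object a `ducknet` model.
#' @param images a (S, S, 3) array, a (S, S, 3, N) array, or a list of
#'   (S, S, 3) arrays with S equal to the model's `input_size` and values in
#'   \[0, 1\].
#' @param batch_size images per forward pass.
#' @param ... unused.
#' @return an (S, S, N) array of per-pixel foreground probabilities.
#' @export
predict.ducknet <- function(object, images, batch_size = 4L, ...) {
  x <- stack_images(images)
  d <- dim(x)
  s <- object$config$input_size
  if (d[1] != s || d[2] != s) {
    stop(sprintf("images are %dx%d but the model expects %dx%d; resize first",
                 d[1], d[2], s, s))
  }
  n <- d[4]
  out <- array(0, c(s, s, n))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    y <- ducknet_forward(object, x[, , , idx, drop = FALSE], training = FALSE)
    out[, , idx] <- y$value
  }
  out
}

# images -> (H, W, 3, N) array
stack_images <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, c(d, length(images)))
    for (i in seq_along(images)) x[, , , i] <- images[[i]]
    return(x)
  }
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  images
}

#' Count learnable parameters
#'
#' @param model a `ducknet` model.
#' @return integer: total number of learnable scalars (weights, biases,
#'   normalization scales/offsets).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ducknet"))
  sum(vapply(nn_params(model$module), function(p) length(p$value), numeric(1)))
}

#' @export
print.ducknet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DUCK-Net (%s blocks): F=%d, input %dx%d, depth %d, %s params\n",
              cfg$block_type, cfg$filters, cfg$input_size, cfg$input_size,
              cfg$depth, format(count_parameters(x), big.mark = ",")))
  ss <- stage_shapes(cfg)
  cat("encoder sides:", paste(ss$side, collapse = " -> "), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the configuration, all parameter values, and the
#' normalization running statistics, so a reloaded model reproduces
#' predictions exactly.
#'
#' @param model a `ducknet` model.
#' @param path file path (conventionally `.rds`).
#' @return `save_ducknet` returns `path` invisibly; `load_ducknet` the model.
#' @export
save_ducknet <- function(model, path) {
  stopifnot(inherits(model, "ducknet"))
  params <- lapply(nn_params(model$module), function(p) p$value)
  states <- lapply(nn_states(model$module), function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(config = unclass(model$config), params = params,
               states = states, format = "duckseg-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_ducknet
#' @export
load_ducknet <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "duckseg-checkpoint-1")) {
    stop("not a duckseg checkpoint: ", path)
  }
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), NULL)])
  model <- build_ducknet(cfg)
  set_model_params(model, ck$params, ck$states)
  model
}

# overwrite a model's parameter values / BN statistics in place
set_model_params <- function(model, params, states = NULL) {
  ps <- nn_params(model$module)
  stopifnot(identical(names(ps), names(params)))
  for (nm in names(ps)) ps[[nm]]$value <- params[[nm]]
  if (!is.null(states)) {
    ss <- nn_states(model$module)
    for (nm in names(ss)) {
      ss[[nm]]$running_mean <- states[[nm]]$running_mean
      ss[[nm]]$running_var <- states[[nm]]$running_var
    }
  }
  invisible(model)
}

get_model_params <- function(model) {
  list(params = lapply(nn_params(model$module), function(p) p$value),
       states = lapply(nn_states(model$module), function(s)
         list(running_mean = s$running_mean, running_var = s$running_var)))
}
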