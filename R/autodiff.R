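#' @useDynLib duckseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-run reverse-mode autodiff.
#
# A node is an environment holding a value (always a 4-D array (H, W, C, N)
# except for scalar losses), an optional gradient, its parent nodes, and a
# backward closure returning one gradient per parent. Graphs are rebuilt on
# every forward pass; parameters are leaf nodes that persist across passes.
# ---------------------------------------------------------------------------

new_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$is_param <- FALSE
  node$.tag <- 0L
  class(node) <- "ag_node"
  node
}

ag_param <- function(value) {
  n <- new_node(value)
  n$is_param <- TRUE
  n
}

ag_const <- function(value) new_node(value)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

.ag <- new.env(parent = emptyenv())
.ag$tag <- 0L

# Post-order (topological) traversal from `root`, iterative so graph depth is
# not limited by R's recursion stack.
ag_topo <- function(root) {
  tag <- .ag$tag <- .ag$tag + 1L
  order <- vector("list", 256L)
  n_ord <- 0L
  frames <- vector("list", 256L)
  nodes <- vector("list", 256L)
  idx <- integer(256L)
  top <- 1L
  nodes[[1L]] <- root
  idx[1L] <- 0L
  root$.tag <- tag
  while (top > 0L) {
    node <- nodes[[top]]
    ps <- node$parents
    if (idx[top] < length(ps)) {
      idx[top] <- idx[top] + 1L
      child <- ps[[idx[top]]]
      if (!identical(child$.tag, tag)) {
        child$.tag <- tag
        top <- top + 1L
        if (top > length(nodes)) {
          length(nodes) <- 2L * top
          length(idx) <- 2L * top
        }
        nodes[[top]] <- child
        idx[top] <- 0L
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) length(order) <- 2L * n_ord
      order[[n_ord]] <- node
      top <- top - 1L
    }
  }
  order[seq_len(n_ord)]
}

#' Backpropagate gradients from a node
#'
#' Accumulates gradients into every ancestor node of `root`, including
#' parameter leaves. Existing gradients in the subgraph are cleared first.
#'
#' @param root node to differentiate (typically a scalar loss).
#' @param seed gradient seeded at `root`; defaults to 1 for scalars and an
#'   all-ones array otherwise.
#' @return invisibly, the topological order used.
#' @keywords internal
ag_backward <- function(root, seed = NULL) {
  order <- ag_topo(root)
  for (n in order) n$grad <- NULL
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  }
  root$grad <- seed
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node)
    ps <- node$parents
    for (j in seq_along(ps)) {
      g <- grads[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(order)
}

# ---- primitive ops --------------------------------------------------------

# 2-D convolution; `pad` defaults to "same" padding for the effective
# (dilated) kernel, which requires odd effective extents for exact symmetry.
ag_conv2d <- function(x, w, b, stride = 1L, dilation = 1L, pad = NULL) {
  wd <- dim(w$value)
  if (is.null(pad)) {
    eff <- (wd[1:2] - 1L) * dilation + 1L
    pad <- (eff - 1L) %/% 2L
  }
  y <- conv2d_fwd_cpp(x$value, w$value, b$value,
                      as.integer(stride), as.integer(dilation),
                      as.integer(pad[1]), as.integer(pad[2]))
  new_node(y, list(x, w, b), backward = function(node) {
    g <- conv2d_bwd_cpp(x$value, w$value, node$grad,
                        as.integer(stride), as.integer(dilation),
                        as.integer(pad[1]), as.integer(pad[2]))
    list(g$dx, g$dw, g$db)
  })
}

ag_relu <- function(x) {
  new_node(relu_fwd_cpp(x$value), list(x),
           function(node) list(relu_bwd_cpp(x$value, node$grad)))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  node <- new_node(y, list(x), function(node) {
    yy <- node$value
    list(node$grad * yy * (1 - yy))
  })
  node
}

# n-ary elementwise sum; operands must agree in shape (checked so that the
# addition-based skip connections fail loudly on any shape drift).
ag_add_n <- function(xs) {
  d <- dim(xs[[1]]$value)
  for (i in seq_along(xs)) {
    if (!identical(dim(xs[[i]]$value), d)) {
      stop(sprintf("addition join: operand %d has shape (%s), expected (%s)",
                   i, paste(dim(xs[[i]]$value), collapse = ","),
                   paste(d, collapse = ",")))
    }
  }
  v <- xs[[1]]$value
  for (i in seq_along(xs)[-1]) v <- v + xs[[i]]$value
  new_node(v, xs, function(node) rep(list(node$grad), length(xs)))
}

ag_add2 <- function(a, b) ag_add_n(list(a, b))

# Parameter-free nearest-neighbour 2x upsampling.
ag_upsample2x <- function(x) {
  d <- dim(x$value)
  ir <- rep(seq_len(d[1]), each = 2L)
  ic <- rep(seq_len(d[2]), each = 2L)
  y <- x$value[ir, ic, , , drop = FALSE]
  new_node(y, list(x), function(node) {
    dy <- node$grad
    ro <- seq(1L, 2L * d[1], by = 2L)
    co <- seq(1L, 2L * d[2], by = 2L)
    g <- dy[ro, co, , , drop = FALSE] + dy[ro + 1L, co, , , drop = FALSE] +
      dy[ro, co + 1L, , , drop = FALSE] + dy[ro + 1L, co + 1L, , , drop = FALSE]
    list(g)
  })
}

# per-channel sum of a (H, W, C, N) array -> length-C vector
chan_sum <- function(a, d) {
  cs <- colSums(matrix(a, ncol = d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# carrying running_mean / running_var for inference mode. eps follows the
# TensorFlow convention (1e-3); the running-statistics momentum is 0.9 so
# that inference statistics are usable within desk-scale (tens of epochs)
# training runs.
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.9, eps = 1e-3) {
  if (training) {
    f <- bn_fwd_cpp(x$value, gamma$value, beta$value, eps)
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * f$mean
    state$running_var <- momentum * state$running_var + (1 - momentum) * f$var
    new_node(f$y, list(x, gamma, beta), function(node) {
      g <- bn_bwd_cpp(f$xhat, node$grad, gamma$value, f$var, eps)
      list(g$dx, g$dgamma, g$dbeta)
    })
  } else {
    d <- dim(x$value)
    HW <- d[1] * d[2]
    inv <- 1 / sqrt(state$running_var + eps)
    y <- bn_inf_cpp(x$value, gamma$value, beta$value, state$running_mean,
                    state$running_var, eps)
    new_node(y, list(x, gamma, beta), function(node) {
      dy <- node$grad
      xhat <- (x$value - rep(state$running_mean, each = HW)) * rep(inv, each = HW)
      list(dy * rep(gamma$value * inv, each = HW),
           chan_sum(dy * xhat, d), chan_sum(dy, d))
    })
  }
}

# Soft Dice loss, computed per image and averaged over the batch:
#   loss = mean_n [ 1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps) ]
ag_dice_loss <- function(p, truth, eps = 1e-6) {
  v <- p$value
  d <- dim(v)
  N <- d[4]
  npix <- prod(d[1:3])
  pm <- matrix(v, ncol = N)
  tm <- matrix(truth, ncol = N)
  inter <- colSums(pm * tm)
  den <- colSums(pm) + colSums(tm) + eps
  num <- 2 * inter + eps
  loss <- mean(1 - num / den)
  new_node(loss, list(p), function(node) {
    dp <- -(2 * tm * rep(den, each = npix) - rep(num, each = npix)) /
      rep(den^2, each = npix) / N
    dp <- dp * node$grad
    dim(dp) <- d
    list(dp)
  })
}
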