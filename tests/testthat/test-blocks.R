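# Block-level contracts: shapes, receptive fields, equivariance, parameter
# economy, and the DUCK branch-sum structure.

test_that("convolution kernel matches a naive direct-summation oracle", {
  set.seed(42)
  cases <- list(list(k = c(3, 3), s = 1, d = 1), list(k = c(3, 3), s = 1, d = 2),
                list(k = c(3, 3), s = 1, d = 4), list(k = c(2, 2), s = 2, d = 1),
                list(k = c(1, 5), s = 1, d = 1), list(k = c(5, 1), s = 1, d = 1),
                list(k = c(1, 1), s = 1, d = 1))
  for (cs in cases) {
    x <- array(rnorm(10 * 12 * 2 * 2), c(10, 12, 2, 2))
    w <- array(rnorm(cs$k[1] * cs$k[2] * 2 * 3), c(cs$k, 2, 3))
    b <- rnorm(3)
    ph <- if (cs$s == 2) 0L else ((cs$k[1] - 1) * cs$d) %/% 2
    pw <- if (cs$s == 2) 0L else ((cs$k[2] - 1) * cs$d) %/% 2
    got <- duckseg:::conv2d_fwd_cpp(x, w, b, cs$s, cs$d, ph, pw)
    want <- naive_conv2d(x, w, b, cs$s, cs$d, ph, pw)
    expect_equal(got, want, tolerance = 1e-12,
                 info = paste("kernel", paste(cs$k, collapse = "x")))
  }
})

test_that("conv/batchnorm/loss gradients match finite differences", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 2, sd = 0.5), c(3, 3, 2, 2))
  b <- rnorm(2)
  gamma <- runif(2, 0.5, 1.5)
  beta <- rnorm(2)
  truth <- array(rbinom(6 * 6 * 1 * 2, 1, 0.5), c(6, 6, 1, 2))
  head_w <- array(rnorm(1 * 1 * 2 * 1), c(1, 1, 2, 1))

  loss_of <- function(xv, wv, bv, gv, bev) {
    xn <- duckseg:::ag_const(xv)
    state <- new.env()
    state$running_mean <- rep(0, 2); state$running_var <- rep(1, 2)
    h <- duckseg:::ag_conv2d(xn, duckseg:::ag_param(wv), duckseg:::ag_param(bv))
    h <- duckseg:::ag_relu(h)
    h <- duckseg:::ag_batchnorm(h, duckseg:::ag_param(gv),
                                duckseg:::ag_param(bev), state, training = TRUE)
    p <- duckseg:::ag_sigmoid(
      duckseg:::ag_conv2d(h, duckseg:::ag_param(head_w),
                          duckseg:::ag_param(0)))
    duckseg:::ag_dice_loss(p, truth)
  }

  # analytic gradients
  xn <- duckseg:::ag_const(x)
  wp <- duckseg:::ag_param(w); bp <- duckseg:::ag_param(b)
  gp <- duckseg:::ag_param(gamma); bep <- duckseg:::ag_param(beta)
  state <- new.env()
  state$running_mean <- rep(0, 2); state$running_var <- rep(1, 2)
  h <- duckseg:::ag_relu(duckseg:::ag_conv2d(xn, wp, bp))
  h <- duckseg:::ag_batchnorm(h, gp, bep, state, training = TRUE)
  p <- duckseg:::ag_sigmoid(
    duckseg:::ag_conv2d(h, duckseg:::ag_param(head_w), duckseg:::ag_param(0)))
  loss <- duckseg:::ag_dice_loss(p, truth)
  duckseg:::ag_backward(loss)

  eps <- 1e-6
  fd <- function(arr, f, n_checks = 12) {
    idx <- sample(length(arr), min(n_checks, length(arr)))
    vapply(idx, function(i) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      (f(a1) - f(a2)) / (2 * eps)
    }, numeric(1)) -> num
    list(idx = idx, num = num)
  }
  chk <- fd(x, function(v) loss_of(v, w, b, gamma, beta)$value)
  expect_equal(xn$grad[chk$idx], chk$num, tolerance = 1e-4)
  chk <- fd(w, function(v) loss_of(x, v, b, gamma, beta)$value)
  expect_equal(wp$grad[chk$idx], chk$num, tolerance = 1e-4)
  chk <- fd(gamma, function(v) loss_of(x, w, b, v, beta)$value)
  expect_equal(gp$grad[chk$idx], chk$num, tolerance = 1e-4)
  chk <- fd(beta, function(v) loss_of(x, w, b, gamma, v)$value)
  expect_equal(bep$grad[chk$idx], chk$num, tolerance = 1e-4)
})

test_that("every block maps (H, W, C) to (H, W, filters)", {
  set.seed(1)
  shapes <- list(c(16, 16, 3), c(12, 20, 1), c(8, 8, 6))
  for (sh in shapes) {
    x <- array(rnorm(prod(sh)), sh)
    for (f in c(1L, 5L)) {
      expect_equal(dim(residual_block(x, f, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(residual_chain(x, f, repeats = 2, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(midscope_block(x, f, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(widescope_block(x, f, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(separated_block(x, f, n = 5, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(duck_block(x, f, n = 5, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(simple_conv_block(x, f, seed = 2)), c(sh[1:2], f))
      expect_equal(dim(strided_downsample(x, f, seed = 2)),
                   c(sh[1:2] %/% 2L, f))
    }
  }
})

test_that("invalid arguments are rejected", {
  x <- array(1, c(8, 8, 2))
  expect_error(residual_block(x, 0), "positive integer")
  expect_error(residual_chain(x, 4, repeats = 4), "1, 2, or 3")
  expect_error(separated_block(x, 4, n = 4), "odd")
  expect_error(duck_block(array(1, c(0, 4, 2)), 4), "positive|dim")
  expect_error(strided_downsample(array(1, c(7, 8, 2)), 4), "even")
  expect_error(residual_block(array(Inf, c(4, 4, 1)), 2), "finite")
})

test_that("gradient-footprint oracle reproduces the simulated kernel sizes", {
  expect_equal(unname(measure_receptive_field(
    block_spec("residual", repeats = 1), 21)), c(5, 5))
  expect_equal(unname(measure_receptive_field(
    block_spec("residual", repeats = 2), 31)), c(9, 9))
  expect_equal(unname(measure_receptive_field(
    block_spec("residual", repeats = 3), 41)), c(13, 13))
  expect_equal(unname(measure_receptive_field("midscope", 31)), c(7, 7))
  expect_equal(unname(measure_receptive_field("widescope", 41)), c(15, 15))
  expect_equal(unname(measure_receptive_field("separated", 41)), c(13, 13))
  expect_equal(unname(measure_receptive_field(
    block_spec("separated", separated_n = 7), 31)), c(7, 7))
  # the DUCK block's footprint is the maximum over its branches
  expect_equal(unname(measure_receptive_field("duck", 41)), c(15, 15))
  expect_equal(unname(measure_receptive_field("simple_conv", 21)), c(5, 5))
  # a single 3x3 convolution: kernel equals footprint
  conv <- duckseg:::with_seed(3, duckseg:::nn_conv2d(1L, 1L, init = "positive"))
  expect_equal(unname(measure_receptive_field(conv, 9)), c(3, 3))
  # saturation must be reported, not silently clipped
  expect_error(measure_receptive_field("widescope", 13), "saturat")
})

test_that("blocks are translation-equivariant away from borders", {
  set.seed(5)
  n <- 24L
  x <- array(rnorm(n * n), c(n, n, 1))
  x_shift <- x
  x_shift[2:n, , ] <- x[1:(n - 1), , ]
  x_shift[1, , ] <- 0
  blocks <- list(
    function(z) residual_block(z, 3, norm = "none", seed = 11),
    function(z) midscope_block(z, 3, norm = "none", seed = 11),
    function(z) widescope_block(z, 3, norm = "none", seed = 11),
    function(z) separated_block(z, 3, n = 5, norm = "none", seed = 11),
    function(z) duck_block(z, 3, n = 5, norm = "none", seed = 11),
    function(z) simple_conv_block(z, 3, norm = "none", seed = 11))
  margin <- 9L  # larger than any block's receptive-field radius
  inner <- (margin + 1L):(n - margin)
  for (blk in blocks) {
    y <- blk(x)
    y_shift <- blk(x_shift)
    expect_equal(y_shift[inner, inner, ], y[inner - 1L, inner, ],
                 tolerance = 1e-12)
  }
})

test_that("duck output is the sum of its six branch outputs (norm disabled)", {
  set.seed(9)
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  duck <- duckseg:::with_seed(4, duckseg:::nn_duck(2L, 3L, norm = "none"))
  xin <- duckseg:::ag_const(array(x, c(dim(x), 1)))
  whole <- duck$forward(xin, training = FALSE)$value
  branch_names <- c("widescope", "midscope", "res1", "res2", "res3", "separated")
  expect_length(intersect(branch_names, names(duck$modules)), 6L)
  parts <- lapply(branch_names, function(nm) {
    duck$modules[[nm]]$forward(xin, training = FALSE)$value
  })
  expect_equal(whole, Reduce(`+`, parts), tolerance = 1e-12)
})

test_that("dilated blocks use fewer parameters than the dense kernels they simulate", {
  ch <- 8L
  dense_7 <- 7 * 7 * ch * ch + ch
  dense_15 <- 15 * 15 * ch * ch + ch
  mid <- block_parameter_count("midscope", ch, ch, norm = "none")
  wide <- block_parameter_count("widescope", ch, ch, norm = "none")
  expect_lt(mid, dense_7)
  expect_lt(wide, dense_15)
  # and the separated block versus its dense NxN counterpart
  sep <- block_parameter_count("separated", ch, ch, separated_n = 13, norm = "none")
  expect_lt(sep, 13 * 13 * ch * ch + ch)
})

test_that("separated convolutions are rank-1: diagonal kernels are unreachable", {
  # effective 2-D impulse response of (1xN then Nx1) is the outer product of
  # the two 1-D kernels
  set.seed(2)
  w1 <- array(rnorm(3), c(1, 3, 1, 1))
  w2 <- array(rnorm(3), c(3, 1, 1, 1))
  imp <- array(0, c(7, 7, 1, 1))
  imp[4, 4, 1, 1] <- 1
  h <- duckseg:::conv2d_fwd_cpp(imp, w1, 0, 1L, 1L, 0L, 1L)
  resp <- duckseg:::conv2d_fwd_cpp(h, w2, 0, 1L, 1L, 1L, 0L)[, , 1, 1]
  want <- outer(w2[, 1, 1, 1], w1[1, , 1, 1])
  # response of a separable pair (flipped to correlation orientation)
  expect_equal(resp[3:5, 3:5], want[3:1, 3:1], tolerance = 1e-12)

  # best rank-1 (separable) least-squares fit to a purely diagonal 3x3
  # kernel: Eckart-Young says the residual is sqrt(s2^2 + s3^2) > 0
  target <- diag(3)
  sv <- svd(target)$d
  resid_rank1 <- sqrt(sum(sv[-1]^2))
  expect_gt(resid_rank1, 0.5)
  # whereas any separable kernel is fitted exactly
  sep_kernel <- outer(c(1, 2, 1), c(1, 0, -1))
  expect_lt(sqrt(sum(svd(sep_kernel)$d[-1]^2)), 1e-12)
})
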