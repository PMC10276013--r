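# ---------------------------------------------------------------------------
# Layer modules. A module is a list with class "nn_module" carrying
#   $params  : named list of ag_param nodes owned directly by the module
#   $modules : named list of child modules
#   $states  : named list of environments with persistent (non-learned) state
#   $forward : function(x_node, training) -> node
# ---------------------------------------------------------------------------

nn_module <- function(forward, params = list(), modules = list(),
                      states = list(), kind = "module") {
  structure(list(forward = forward, params = params, modules = modules,
                 states = states, kind = kind),
            class = "nn_module")
}

#' Collect the learnable parameters of a module
#'
#' @param module an `nn_module` (blocks and whole models are modules).
#' @param prefix name prefix used for the recursive flattening.
#' @return named list of parameter nodes.
#' @keywords internal
nn_params <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$modules)) {
    out <- c(out, nn_params(module$modules[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

nn_states <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$states)) {
    out[[paste0(prefix, nm)]] <- module$states[[nm]]
  }
  for (nm in names(module$modules)) {
    out <- c(out, nn_states(module$modules[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Variance-scaling (He fan-in) initialization; "positive" draws strictly
# positive weights so that gradient footprints cannot cancel — used by the
# receptive-field oracle.
conv_init <- function(kh, kw, in_ch, out_ch, init = "he") {
  n <- kh * kw * in_ch * out_ch
  w <- switch(init,
    he = stats::rnorm(n, sd = sqrt(2 / (kh * kw * in_ch))),
    positive = stats::runif(n, 0.05, 0.15),
    stop("unknown init: ", init))
  array(w, dim = c(kh, kw, in_ch, out_ch))
}

nn_conv2d <- function(in_ch, out_ch, kh = 3L, kw = 3L, stride = 1L,
                      dilation = 1L, activation = "relu", init = "he",
                      pad = NULL) {
  w <- ag_param(conv_init(kh, kw, in_ch, out_ch, init))
  b <- ag_param(numeric(out_ch))
  forward <- function(x, training = FALSE) {
    if (stride > 1L) {
      d <- dim(x$value)
      if (d[1] %% stride != 0L || d[2] %% stride != 0L) {
        stop(sprintf("strided convolution needs spatial dims divisible by %d, got %dx%d",
                     stride, d[1], d[2]))
      }
    }
    y <- ag_conv2d(x, w, b, stride = stride, dilation = dilation, pad = pad)
    switch(activation,
      relu = ag_relu(y),
      sigmoid = ag_sigmoid(y),
      linear = y,
      stop("unknown activation: ", activation))
  }
  nn_module(forward, params = list(w = w, b = b), kind = "conv2d")
}

nn_batchnorm <- function(channels) {
  gamma <- ag_param(rep(1, channels))
  beta <- ag_param(rep(0, channels))
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, channels)
  state$running_var <- rep(1, channels)
  forward <- function(x, training = FALSE) {
    ag_batchnorm(x, gamma, beta, state, training = training)
  }
  nn_module(forward, params = list(gamma = gamma, beta = beta),
            states = list(bn = state), kind = "batchnorm")
}

nn_identity <- function() {
  nn_module(function(x, training = FALSE) x, kind = "identity")
}

# optional batch norm, controlled by `norm` ("batch" or "none")
nn_norm <- function(channels, norm) {
  if (identical(norm, "batch")) nn_batchnorm(channels) else nn_identity()
}
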