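# Shared fixtures and independent oracles. Everything is generated in code;
# the smoke-scale training runs are cached across test files (training and
# acceptance tests share the same replicates).

# --- independent naive convolution oracle (pure R, direct summation) --------
naive_conv2d <- function(x, w, b, stride = 1, dil = 1, ph = NULL, pw = NULL) {
  d <- dim(x); wd <- dim(w)
  if (is.null(ph)) ph <- ((wd[1] - 1) * dil) %/% 2
  if (is.null(pw)) pw <- ((wd[2] - 1) * dil) %/% 2
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  Ho <- (H + 2 * ph - ((kh - 1) * dil + 1)) %/% stride + 1
  Wo <- (W + 2 * pw - ((kw - 1) * dil + 1)) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (oi in 1:Ho) for (oj in 1:Wo) {
    acc <- b[co]
    for (ci in 1:Cin) for (ki in 1:kh) for (kj in 1:kw) {
      ii <- (oi - 1) * stride - ph + (ki - 1) * dil + 1
      ij <- (oj - 1) * stride - pw + (kj - 1) * dil + 1
      if (ii >= 1 && ii <= H && ij >= 1 && ij <= W) {
        acc <- acc + x[ii, ij, ci, n] * w[ki, kj, ci, co]
      }
    }
    y[oi, oj, co, n] <- acc
  }
  y
}

# --- independent naive metric formulas ---------------------------------------
naive_metrics <- function(pred, truth) {
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  tn <- sum((1 - pred) * (1 - truth))
  c(dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    jaccard = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    precision = if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp),
    recall = if (tp + fn == 0) (if (fp == 0) 1 else 0) else tp / (tp + fn),
    accuracy = (tp + tn) / length(pred))
}

random_mask <- function(h, w, p = 0.4) {
  matrix(stats::rbinom(h * w, 1, p), h, w)
}

# --- smoke-scale training runs, cached across test files ---------------------
# Desk-scale stand-in for the full protocol: F = 4 at 64 x 64 on 200
# synthetic samples, <= 30 epochs (12 used, chosen for the CPU budget; see
# the methods vignette), RMSprop lr 1e-3, no augmentation, batch 4, 80:10:10
# split. One seed controls dataset, split, weights, and shuffling of a
# replicate.
SMOKE_EPOCHS <- 12L
SMOKE_SEEDS <- 1:3

smoke_cache <- new.env(parent = emptyenv())

smoke_dataset <- function(seed) {
  key <- paste0("ds_", seed)
  if (is.null(smoke_cache[[key]])) {
    smoke_cache[[key]] <- generate_dataset(
      synth_config(n_samples = 200, size = 64, seed = seed))
  }
  smoke_cache[[key]]
}

smoke_run <- function(block_type, seed) {
  key <- paste0(block_type, "_", seed)
  if (is.null(smoke_cache[[key]])) {
    ds <- smoke_dataset(seed)
    cfg <- train_config(
      model = model_config(filters = 4L, input_size = 64L, depth = 5L,
                           block_type = block_type, seed = seed),
      learning_rate = 1e-3, batch_size = 4L, epochs = SMOKE_EPOCHS,
      augment_enabled = FALSE, split = split_spec(seed = seed), seed = seed)
    fit <- train(cfg, ds)
    report <- evaluate(fit$model, ds, ids = fit$split$test)
    smoke_cache[[key]] <- list(fit = fit, report = report,
                               test_dice = report$means[["dice"]])
  }
  smoke_cache[[key]]
}

smoke_dice <- function(block_type) {
  vapply(SMOKE_SEEDS, function(s) smoke_run(block_type, s)$test_dice,
         numeric(1))
}
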