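# Training loop: defaults, determinism, checkpointing, evaluation helpers.
# The smoke-scale learning runs themselves are asserted in test-acceptance.R;
# here we reuse their cached results where available.

tiny_train_cfg <- function(seed = 1L, epochs = 2L, block_type = "duck") {
  train_config(
    model = model_config(filters = 2L, input_size = 32L, depth = 3L,
                         block_type = block_type, seed = seed,
                         separated_n = 5L),
    learning_rate = 1e-3, batch_size = 4L, epochs = epochs,
    augment_enabled = FALSE, split = split_spec(seed = seed), seed = seed)
}

tiny_data <- function(seed = 21L, n = 12L) {
  generate_dataset(synth_config(n_samples = n, size = 32, seed = seed))
}

test_that("training defaults are the published protocol", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$epochs, 600L)
  expect_equal(cfg$checkpoint, "best")
  expect_equal(cfg$split$train_fraction, 0.8)
  expect_equal(cfg$model$input_size, 352L)
  expect_s3_class(cfg$augment, "augment_config")
})

test_that("identical seeds reproduce identical training histories", {
  ds <- tiny_data()
  f1 <- train(tiny_train_cfg(seed = 3), ds)
  f2 <- train(tiny_train_cfg(seed = 3), ds)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$split, f2$split)
  x <- array(0.5, c(32, 32, 3, 1))
  expect_identical(predict(f1$model, x), predict(f2$model, x))
})

test_that("history has one row per epoch with losses in [0, 1]", {
  fit <- train(tiny_train_cfg(seed = 4, epochs = 3), tiny_data())
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(fit$history$train_loss >= 0 & fit$history$train_loss <= 1))
  expect_true(all(fit$history$val_loss >= 0 & fit$history$val_loss <= 1))
  expect_true(all(fit$history$val_dice >= 0 & fit$history$val_dice <= 1))
})

test_that("best-validation checkpoint restore reproduces the recorded dice", {
  ds <- tiny_data()
  fit <- train(tiny_train_cfg(seed = 5, epochs = 3), ds)
  expect_equal(fit$best_val_dice, max(fit$history$val_dice))
  rep_val <- evaluate(fit$model, ds, ids = fit$split$val)
  expect_equal(rep_val$means[["dice"]], fit$best_val_dice, tolerance = 1e-12)
})

test_that("the augmentation switch changes batches, not the graph", {
  ds <- tiny_data()
  cfg_off <- tiny_train_cfg(seed = 6)
  cfg_off$augment_enabled <- FALSE
  cfg_on <- tiny_train_cfg(seed = 6)
  cfg_on$augment_enabled <- TRUE
  f_off <- train(cfg_off, ds)
  f_on2 <- train(cfg_on, ds)
  expect_equal(count_parameters(f_off$model), count_parameters(f_on2$model))
})

test_that("evaluate honours manifests and degenerate predictors", {
  ds <- tiny_data()
  fit <- train(tiny_train_cfg(seed = 7), ds)

  # oracle upper bound: evaluating truth masks as predictions gives 1
  truths <- lapply(ds, `[[`, "mask")
  rep_oracle <- evaluate_set(truths, truths)
  expect_equal(unname(rep_oracle$means), rep(1, 5))

  # an all-background predictor has recall 0 (every synthetic image has
  # foreground): force the head bias very negative
  m <- build_ducknet(fit$model$config)
  head <- m$module$modules$head$params
  head$w$value[] <- 0    # logits identically -50 -> probabilities ~ 0
  head$b$value <- -50
  rep_bg <- evaluate(m, ds)
  expect_equal(rep_bg$means[["recall"]], 0)

  # manifest subset and repeat-evaluation determinism
  rep_a <- evaluate(fit$model, ds, ids = fit$split$test)
  rep_b <- evaluate(fit$model, ds, ids = fit$split$test)
  expect_identical(rep_a$per_image, rep_b$per_image)
  expect_equal(rep_a$n_images, length(fit$split$test))
  expect_error(evaluate(fit$model, ds, ids = "missing_id"), "missing_id")

  # manifest file path
  dir <- withr::local_tempdir()
  writeLines(fit$split$test, file.path(dir, "test.txt"))
  rep_c <- evaluate(fit$model, ds, ids = file.path(dir, "test.txt"))
  expect_identical(rep_c$per_image, rep_a$per_image)
})

test_that("cross-dataset evaluation runs over the full foreign set", {
  ds_a <- tiny_data(seed = 21)
  ds_b <- generate_dataset(synth_config(n_samples = 6, size = 32,
                                        contrast_gap = 0.1, seed = 99))
  fit <- train(tiny_train_cfg(seed = 8), ds_a)
  rep_self <- cross_evaluate(fit$model, ds_a)
  expect_equal(rep_self$n_images, length(ds_a))
  rep_cross <- cross_evaluate(fit$model, ds_b)
  expect_equal(rep_cross$n_images, length(ds_b))
  expect_true(all(rep_cross$means >= 0 & rep_cross$means <= 1))
  # self-consistency with evaluate on the full set
  expect_identical(rep_self$per_image, evaluate(fit$model, ds_a)$per_image)
})

test_that("training configuration round-trips through JSON", {
  dir <- withr::local_tempdir()
  cfg <- tiny_train_cfg(seed = 13, epochs = 5)
  cfg$augment <- augment_config(shear_symmetric = FALSE)
  path <- file.path(dir, "config.json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$model, cfg$model)
  expect_equal(back$augment, cfg$augment)
  expect_equal(back$split, cfg$split)
  expect_equal(back$epochs, cfg$epochs)
  expect_equal(back$learning_rate, cfg$learning_rate)
})

test_that("a trained model degrades as polyp contrast fades (sweep trend)", {
  # evaluation-only reading of the difficulty sweep: the smoke models are
  # trained at the default contrast and tested at decreasing gaps
  base <- synth_config(n_samples = 20, size = 64, seed = 77)
  sweep <- difficulty_sweep(base, gaps = c(0.35, 0.15, 0))
  dices <- sapply(SMOKE_SEEDS, function(s) {
    model <- smoke_run("duck", s)$fit$model
    sapply(sweep, function(ds) cross_evaluate(model, ds)$means[["dice"]])
  })
  trend <- rowMeans(dices)
  expect_gt(trend[["gap_0.35"]], trend[["gap_0"]])
  expect_true(all(diff(trend) <= 0.05))  # non-increasing up to noise
})
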