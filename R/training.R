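# ---------------------------------------------------------------------------
# Training loop: RMSprop on the soft Dice loss over augmented batches, with
# per-epoch validation and best-validation-Dice checkpointing.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults are the published protocol: RMSprop with learning rate 1e-4,
#' batch size 4, 600 epochs, Dice loss, augmented training split, 80:10:10
#' random split. RMSprop decay/epsilon beyond the learning rate follow the
#' usual framework defaults (rho 0.9, eps 1e-7).
#'
#' @param model a [model_config()].
#' @param learning_rate RMSprop learning rate.
#' @param batch_size images per optimization step.
#' @param epochs full passes over the (re-augmented) training split.
#' @param augment an [augment_config()].
#' @param augment_enabled disable to train on raw samples (ablation flag).
#' @param split a [split_spec()].
#' @param threshold binarization threshold used for validation Dice.
#' @param checkpoint `"best"` (restore the best-validation-Dice weights,
#'   default) or `"final"` (keep the last epoch).
#' @param seed master seed for shuffling and augmentation sampling.
#' @param rmsprop_rho,rmsprop_eps optimizer constants.
#' @param verbose print a line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(model = model_config(), learning_rate = 1e-4,
                         batch_size = 4L, epochs = 600L,
                         augment = augment_config(), augment_enabled = TRUE,
                         split = split_spec(), threshold = 0.5,
                         checkpoint = c("best", "final"), seed = 1L,
                         rmsprop_rho = 0.9, rmsprop_eps = 1e-7,
                         verbose = FALSE) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(model = model, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 augment_enabled = isTRUE(augment_enabled), split = split,
                 threshold = threshold, checkpoint = checkpoint,
                 seed = as.integer(seed), rmsprop_rho = rmsprop_rho,
                 rmsprop_eps = rmsprop_eps, verbose = isTRUE(verbose)),
            class = "train_config")
}

resolve_samples <- function(data, target_size) {
  if (is.character(data) && length(data) == 1L) {
    return(load_dataset(data, target_size))
  }
  if (inherits(data, "synth_config")) return(generate_dataset(data))
  if (is.list(data)) return(data)
  stop("`data` must be a directory, a synth_config, or a list of samples")
}

sample_ids <- function(samples) {
  vapply(samples, function(s) s$id, character(1))
}

stack_batch <- function(samples, idx, augment = NULL) {
  s <- dim(samples[[idx[1]]]$image)[1]
  x <- array(0, c(s, s, 3L, length(idx)))
  y <- array(0, c(s, s, 1L, length(idx)))
  for (j in seq_along(idx)) {
    sm <- samples[[idx[j]]]
    if (!is.null(augment)) {
      a <- augment_pair(sm$image, sm$mask, augment)
      x[, , , j] <- a$image
      y[, , 1, j] <- a$mask
    } else {
      x[, , , j] <- sm$image
      y[, , 1, j] <- sm$mask
    }
  }
  list(x = x, y = y)
}

#' Train a DUCK-Net
#'
#' Optimizes the soft Dice loss with RMSprop over the augmented training
#' split. Every source of randomness (split, weight initialization, epoch
#' shuffling, augmentation draws) is derived from the configured seeds, so
#' identical configurations reproduce identical histories.
#'
#' @param config a [train_config()].
#' @param data a dataset directory (images/ + masks/), a [synth_config()],
#'   or a list of sample pairs.
#' @return list with `model` (weights per the checkpoint policy), `history`
#'   (data.frame: epoch, train_loss, val_loss, val_dice), `best_epoch`, and
#'   the `split` id lists.
#' @export
train <- function(config, data) {
  stopifnot(inherits(config, "train_config"))
  samples <- resolve_samples(data, config$model$input_size)
  if (length(samples) < 3L) stop("need at least 3 samples to train")
  ids <- sample_ids(samples)
  split <- split_dataset(ids, config$split)
  train_idx <- match(split$train, ids)
  val_idx <- match(split$val, ids)
  if (length(train_idx) == 0L) stop("empty training split")

  model <- build_ducknet(config$model)
  params <- nn_params(model$module)
  cache <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  lr <- config$learning_rate
  rho <- config$rmsprop_rho
  eps <- config$rmsprop_eps

  history <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                        val_loss = NA_real_, val_dice = NA_real_)
  best <- list(dice = -Inf, epoch = NA_integer_, snapshot = NULL)
  val_batch <- if (length(val_idx)) stack_batch(samples, val_idx) else NULL

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order <- sample(train_idx)
      losses <- c()
      for (start in seq(1L, length(order), by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1L, length(order))]
        batch <- stack_batch(samples, idx,
                             augment = if (config$augment_enabled) config$augment)
        out <- ducknet_forward(model, batch$x, training = TRUE)
        loss <- ag_dice_loss(out, batch$y)
        if (!is.finite(loss$value)) {
          stop(sprintf("non-finite training loss at epoch %d; aborting", epoch))
        }
        losses <- c(losses, loss$value)
        ag_backward(loss)
        for (nm in names(params)) {
          p <- params[[nm]]
          g <- p$grad
          if (is.null(g)) next
          cache[[nm]] <- rho * cache[[nm]] + (1 - rho) * g * g
          p$value <- p$value - lr * g / (sqrt(cache[[nm]]) + eps)
        }
      }
      history$train_loss[epoch] <- mean(losses)
      if (!is.null(val_batch)) {
        vout <- ducknet_forward(model, val_batch$x, training = FALSE)
        history$val_loss[epoch] <- ag_dice_loss(vout, val_batch$y)$value
        rep_val <- evaluate_set(array(vout$value, dim(vout$value)[c(1, 2, 4)]),
                                array(val_batch$y, dim(val_batch$y)[c(1, 2, 4)]),
                                threshold = config$threshold)
        history$val_dice[epoch] <- rep_val$means[["dice"]]
        if (rep_val$means[["dice"]] > best$dice) {
          best <- list(dice = rep_val$means[["dice"]], epoch = epoch,
                       snapshot = get_model_params(model))
        }
      }
      if (config$verbose) {
        cat(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val dice %.4f\n",
                    epoch, history$train_loss[epoch],
                    history$val_loss[epoch] %||% NA,
                    history$val_dice[epoch] %||% NA))
      }
    }
  })

  if (config$checkpoint == "best" && !is.null(best$snapshot)) {
    set_model_params(model, best$snapshot$params, best$snapshot$states)
  }
  list(model = model, history = history,
       best_epoch = if (is.na(best$epoch)) config$epochs else best$epoch,
       best_val_dice = if (is.finite(best$dice)) best$dice else NA_real_,
       split = split)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model on a dataset split
#'
#' @param model a `ducknet`.
#' @param data dataset directory, [synth_config()], or list of samples.
#' @param ids optional id subset (e.g. one entry of a [split_dataset()]
#'   result, or a manifest file path).
#' @param threshold binarization threshold.
#' @param batch_size forward-pass batch size.
#' @return a [evaluate_set()] metrics report.
#' @export
evaluate <- function(model, data, ids = NULL, threshold = 0.5,
                     batch_size = 4L) {
  samples <- resolve_samples(data, model$config$input_size)
  all_ids <- sample_ids(samples)
  if (is.character(ids) && length(ids) == 1L && file.exists(ids)) {
    ids <- readLines(ids)
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, all_ids)
    if (length(miss)) {
      stop("ids not present in dataset: ", paste(miss, collapse = ", "))
    }
    samples <- samples[match(ids, all_ids)]
  }
  imgs <- lapply(samples, function(s) s$image)
  probs <- predict(model, imgs, batch_size = batch_size)
  truths <- lapply(samples, function(s) s$mask)
  evaluate_set(probs, truths, threshold = threshold,
               ids = sample_ids(samples))
}

#' Cross-dataset evaluation
#'
#' Evaluates a trained model on the full foreign dataset (no split), the
#' protocol used to probe generalization across datasets.
#'
#' @inheritParams evaluate
#' @return a metrics report over every sample of `data`.
#' @export
cross_evaluate <- function(model, data, threshold = 0.5, batch_size = 4L) {
  evaluate(model, data, ids = NULL, threshold = threshold,
           batch_size = batch_size)
}

#' Write a training history to CSV
#'
#' @param history the `history` data.frame from [train()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
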