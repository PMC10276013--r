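# JSON round-trip of the structured configuration file. Keys mirror the
# configuration constructors: model.*, augment.*, split.*, and the top-level
# training fields.

#' Write / read a training configuration as JSON
#'
#' @param config a [train_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `train_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  x <- unclass(config)
  x$model <- unclass(x$model)
  x$augment <- unclass(x$augment)
  x$split <- unclass(x$split)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- do.call(model_config, x$model)
  augment <- do.call(augment_config, as.list(x$augment))
  split <- do.call(split_spec, x$split)
  rest <- x[setdiff(names(x), c("model", "augment", "split"))]
  do.call(train_config, c(list(model = model, augment = augment,
                               split = split), rest))
}
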