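# YAML configuration for model and training settings.

#' Read / write a model + training configuration
#'
#' A configuration file is a YAML mapping with optional sections `model`
#' (arguments to [model_config()]), `train` (arguments to [fit()]:
#' `epochs`, `batch_size`, `learning_rate`, `weight_decay`, `patience`,
#' `focal` with `gamma`/`alpha`, `focal_only`), `augment` (arguments to
#' [augment_params()]) and `search` (grids for [random_search()];
#' defaults to [search_space()]).
#'
#' @param path YAML file path.
#' @return `read_config`: a list with `model` (a `model_config`), `train`
#'   (list), `augment` (an `augment_params`), `search` (list of grids).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model <- do.call(model_config, raw$model %||% list())
  aug <- do.call(augment_params, raw$augment %||% list())
  train <- raw$train %||% list()
  if (!is.null(train$focal)) {
    train$focal <- focal_params(gamma = train$focal$gamma %||% 1.5,
                                alpha = unlist(train$focal$alpha %||% 1))
  }
  search <- raw$search %||% search_space()
  list(model = model, train = train, augment = aug, search = search)
}

#' @rdname read_config
#' @param config List as returned by `read_config` (or any subset of its
#'   sections in plain-list form).
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, "focal_params") || inherits(x, "augment_params") ||
        inherits(x, "model_config")) {
      x <- unclass(x)
    }
    if (is.list(x)) lapply(x, strip) else x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
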