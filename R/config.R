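# YAML experiment configuration: a structured mirror of cohort_config() +
# fl_config(), so runs are reproducible from a single text file.

#' Read an experiment configuration from YAML
#'
#' Recognized top-level keys (all optional; omitted values take the package
#' defaults, which are the study's published settings):
#'
#' ```yaml
#' cohort:
#'   n_mild: 220
#'   n_severe: 188
#'   n_features: 40
#'   missing_rate: 0
#'   features:            # overrides the built-in Table-style specs
#'     - {name: age, kind: continuous,
#'        mild: [77.6, 80.0], severe: [80.2, 82.8], bounds: [18, 110]}
#'     - {name: sex, kind: binary, mild: 188, severe: 157}
#' fl:
#'   k: 3
#'   rounds: 350
#'   epochs: 5
#'   batch_size: 10
#'   eta: 0.001
#'   split: [7, 3]
#'   hidden: [32, 16]
#'   activation: relu
#'   weighted: false
#' samples_per_client: 136
#' missing_threshold: 0.10
#' ```
#'
#' @param path Path to a YAML (or JSON) file.
#' @return An [experiment_spec()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_experiment_spec(cfg)
}

#' @rdname read_experiment_config
#' @param x A named list with the structure above.
#' @export
as_experiment_spec <- function(x) {
  co <- x$cohort %||% list()
  specs <- if (!is.null(co$features)) {
    lapply(co$features, function(f)
      feature_spec(f$name, f$kind %||% "continuous",
                   mild = unlist(f$mild), severe = unlist(f$severe),
                   bounds = if (!is.null(f$bounds)) unlist(f$bounds)))
  } else default_feature_specs()
  cohort <- cohort_config(
    n_mild = co$n_mild %||% 220, n_severe = co$n_severe %||% 188,
    specs = specs, n_features = co$n_features %||% 40,
    missing_rate = co$missing_rate %||% 0,
    ci_n = unlist(co$ci_n %||% c(mild = 220, severe = 188)))
  f <- x$fl %||% list()
  fl <- fl_config(
    k = f$k %||% 3, rounds = f$rounds %||% 350, eta = f$eta %||% 0.001,
    epochs = f$epochs %||% 5, batch_size = f$batch_size %||% 10,
    split = unlist(f$split %||% c(7, 3)),
    hidden = unlist(f$hidden %||% c(32, 16)),
    activation = f$activation %||% "relu",
    weighted = f$weighted %||% FALSE)
  experiment_spec(cohort = cohort, fl = fl,
                  samples_per_client = x$samples_per_client,
                  missing_threshold = x$missing_threshold %||% 0.10)
}

#' Write a run manifest for audit
#'
#' Records the package version, the seed, and the resolved configuration as
#' JSON next to a run's outputs.
#'
#' @param dir Output directory (created if needed).
#' @param spec The [experiment_spec()] used.
#' @param seed The master seed.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, spec, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  fl <- spec$fl
  obj <- list(
    package = "fedcopd",
    version = as.character(utils::packageVersion("fedcopd")),
    seed = seed,
    cohort = list(n_mild = spec$cohort$n_mild,
                  n_severe = spec$cohort$n_severe,
                  n_features = spec$cohort$n_features,
                  missing_rate = spec$cohort$missing_rate),
    fl = list(k = fl$k, rounds = fl$rounds, eta = fl$train$eta,
              epochs = fl$train$epochs, batch_size = fl$train$batch_size,
              split = fl$split, hidden = fl$hidden,
              activation = fl$activation, weighted = fl$weighted),
    samples_per_client = spec$samples_per_client,
    missing_threshold = spec$missing_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
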