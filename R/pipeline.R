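# One-call pipeline: simulate -> extract -> train -> evaluate, driven by a
# single configuration object and one master seed.

#' Pipeline configuration
#'
#' Bundles the stage configurations of the full pipeline. A single master
#' seed deterministically derives every stage seed (see [derive_seed()]), so
#' one integer reproduces the whole run. The configuration round-trips
#' losslessly through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param generator A [generator_config()]; its own seed is overridden by a
#'   stream derived from `seed`.
#' @param extraction A [feature_params()].
#' @param grid A [cslr_grid()] tibble.
#' @param test_fraction Held-out fraction.
#' @param k Cross-validation folds.
#' @param cv_metric Grid-search metric.
#' @param bootstrap_reps Bootstrap replicates.
#' @param seed Master seed.
#' @return A list of class `tof_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            extraction = feature_params(),
                            grid = cslr_grid(),
                            test_fraction = 0.4,
                            k = 5L,
                            cv_metric = "f1",
                            bootstrap_reps = 1000L,
                            seed = 42L) {
  structure(
    list(
      generator = generator,
      extraction = extraction,
      grid = grid,
      test_fraction = check_fraction(test_fraction, "test_fraction"),
      k = check_count(k, "k", 2L),
      cv_metric = cv_metric,
      bootstrap_reps = check_count(bootstrap_reps, "bootstrap_reps", 100L),
      seed = check_count(abs(seed), "seed", 0L)
    ),
    class = "tof_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `tof_pipeline_config`.
#' @param path File path (JSON).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "tof_pipeline_config"))
  payload <- list(
    generator = unclass(config$generator),
    extraction = unclass(config$extraction),
    grid = config$grid,
    test_fraction = config$test_fraction,
    k = config$k,
    cv_metric = config$cv_metric,
    bootstrap_reps = config$bootstrap_reps,
    seed = config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- p$generator
  mix <- unlist(gen$anomaly_mix)
  if (is.null(names(mix))) names(mix) <- anomaly_types()
  gen$anomaly_mix <- mix
  pipeline_config(
    generator = do.call(generator_config, gen),
    extraction = do.call(feature_params, p$extraction),
    grid = tibble::tibble(
      l2_lambda = p$grid$l2_lambda,
      w_outlier = as.list(p$grid$w_outlier)
    ),
    test_fraction = p$test_fraction,
    k = p$k,
    cv_metric = p$cv_metric,
    bootstrap_reps = p$bootstrap_reps,
    seed = p$seed
  )
}

#' Run the full simulate-extract-train-evaluate pipeline
#'
#' @param config A [pipeline_config()].
#' @param with_ci,with_learning_curves,with_comparison Stage toggles passed
#'   to [run_experiment()].
#' @return A list of class `tof_pipeline_result` with elements `recordings`,
#'   `features`, `experiment`, and the `config` used.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 42)
#' res <- run_pipeline(cfg)
#' tidy(res$experiment)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(),
                         with_ci = TRUE,
                         with_learning_curves = TRUE,
                         with_comparison = TRUE) {
  stopifnot(inherits(config, "tof_pipeline_config"))
  gen <- config$generator
  gen$seed <- derive_seed(config$seed, "simulate")
  recordings <- simulate_dataset(gen)
  features <- build_feature_table(recordings, config$extraction)
  experiment <- run_experiment(
    features,
    seed = config$seed,
    test_fraction = config$test_fraction,
    k = config$k,
    grid = config$grid,
    cv_metric = config$cv_metric,
    bootstrap_reps = config$bootstrap_reps,
    with_ci = with_ci,
    with_learning_curves = with_learning_curves,
    with_comparison = with_comparison
  )
  structure(
    list(recordings = recordings, features = features,
         experiment = experiment, config = config),
    class = "tof_pipeline_result"
  )
}

#' @export
print.tof_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<tof_pipeline_result> %d recordings -> %d feature rows (master seed %d)\n",
    nrow(x$recordings), nrow(x$features), x$config$seed
  ))
  print(x$experiment)
  invisible(x)
}
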