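# End-to-end experiment: split -> grid search -> refit -> test evaluation,
# for the basic and the engineered feature set on identical partitions.

eval_report <- function(fit, data, tag, partition, reps, seed, label_col,
                        with_ci = TRUE) {
  truth <- as_label01(data[[label_col]])
  score <- predict_proba(fit, data)
  pred <- as.integer(score >= fit$config$threshold)
  m <- classification_metrics(truth, pred, score)
  m$model_tag <- tag
  m$partition <- partition
  if (with_ci) {
    cis <- purrr::map(
      c("f1", "precision", "recall", "roc_auc"),
      function(met) {
        bootstrap_ci(truth, pred, score,
                     metric = met, reps = reps,
                     seed = derive_seed(seed, paste(tag, partition, met)))
      }
    ) |> dplyr::bind_rows()
    for (i in seq_len(nrow(cis))) {
      m[[paste0(cis$metric[i], "_low")]] <- cis$low[i]
      m[[paste0(cis$metric[i], "_high")]] <- cis$high[i]
    }
  }
  m[, c("model_tag", "partition",
        setdiff(names(m), c("model_tag", "partition")))]
}

#' Run the full outlier-detection experiment
#'
#' Mirrors the complete evaluation protocol on one dataset: a stratified
#' train/test split (default 60/40), per-feature-set stratified k-fold grid
#' search over the CSLR hyperparameters on the training rows only, a refit of
#' each winning configuration on the full training set, evaluation on the
#' identical held-out test rows (F1, precision, recall, rank ROC-AUC, with
#' stratified percentile-bootstrap 95% CIs), learning curves, and a paired
#' Wilcoxon signed-rank comparison of the two models over repeated-CV fold
#' scores. The held-out test rows never enter grid search, standardisation
#' statistics, or the learning curves.
#'
#' @param data A feature table ([build_feature_table()]) or a recordings
#'   tibble (features are then extracted with default [feature_params()]).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param test_fraction Held-out fraction (default 0.40).
#' @param k Cross-validation folds (default 5).
#' @param grid Hyperparameter grid, see [cslr_grid()].
#' @param cv_metric Metric maximised by the grid search, `"f1"` (default) or
#'   `"roc_auc"`.
#' @param base_config A [cslr_config()] for non-searched settings.
#' @param bootstrap_reps Bootstrap replicates for the CIs.
#' @param feature_sets Named list of feature-column vectors to compare.
#' @param with_ci,with_learning_curves,with_comparison Stage toggles.
#' @param label_col Label column name.
#' @return A list of class `tof_experiment`: `split`, per-set `grid_search`,
#'   `fits`, `reports` (tibble of train/test metric rows), `learning_curves`,
#'   `comparison` (Wilcoxon tibble), `seed`.
#' @export
run_experiment <- function(data,
                           seed = 42L,
                           test_fraction = 0.4,
                           k = 5L,
                           grid = cslr_grid(),
                           cv_metric = "f1",
                           base_config = cslr_config(),
                           bootstrap_reps = 1000L,
                           feature_sets = list(basic = basic_features(),
                                               engineered = engineered_features()),
                           with_ci = TRUE,
                           with_learning_curves = TRUE,
                           with_comparison = TRUE,
                           label_col = "label") {
  if ("signal" %in% names(data)) {
    data <- build_feature_table(data)
  }
  split <- stratified_split(data, test_fraction,
                            seed = derive_seed(seed, "split"),
                            label_col = label_col)

  grids <- list()
  fits <- list()
  reports <- list()
  curves <- list()
  for (tag in names(feature_sets)) {
    feats <- feature_sets[[tag]]
    gs <- grid_search_cv(split$train, feats, grid, k, cv_metric,
                         seed = derive_seed(seed, paste0("cv_", tag)),
                         base_config = base_config, label_col = label_col)
    fit <- cslr_fit(split$train, feats, gs$best_config, label_col)
    grids[[tag]] <- gs
    fits[[tag]] <- fit
    reports[[paste(tag, "train")]] <- eval_report(
      fit, split$train, tag, "train", bootstrap_reps, seed, label_col, with_ci
    )
    reports[[paste(tag, "test")]] <- eval_report(
      fit, split$test, tag, "test", bootstrap_reps, seed, label_col, with_ci
    )
    if (with_learning_curves) {
      lc <- learning_curves(split$train, feats, gs$best_config,
                            k = k, seed = derive_seed(seed, paste0("lc_", tag)),
                            label_col = label_col)
      lc$model_tag <- tag
      curves[[tag]] <- lc
    }
  }

  comparison <- NULL
  cv_pairs <- NULL
  if (with_comparison && length(feature_sets) == 2L) {
    tags <- names(feature_sets)
    cv_pairs <- repeated_cv_scores(
      split$train,
      feature_sets[[tags[1]]], feature_sets[[tags[2]]],
      grids[[tags[1]]]$best_config, grids[[tags[2]]]$best_config,
      k = k, times = 5L, metric = cv_metric,
      seed = derive_seed(seed, "wilcoxon"), label_col = label_col
    )
    comparison <- compare_models(cv_pairs$score_a, cv_pairs$score_b)
    comparison$model_a <- tags[1]
    comparison$model_b <- tags[2]
  }

  structure(
    list(
      split = split,
      grid_search = grids,
      fits = fits,
      reports = dplyr::bind_rows(reports),
      learning_curves = if (length(curves)) dplyr::bind_rows(curves) else NULL,
      comparison = comparison,
      cv_pairs = cv_pairs,
      seed = seed
    ),
    class = "tof_experiment"
  )
}

#' @export
print.tof_experiment <- function(x, ...) {
  cat("<tof_experiment>\n")
  cat(sprintf(
    "  split: train n = %d (%d outliers), test n = %d (%d outliers)\n",
    nrow(x$split$train), sum(as_label01(x$split$train$label)),
    nrow(x$split$test), sum(as_label01(x$split$test$label))
  ))
  r <- x$reports[x$reports$partition == "test", ]
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      "  %s (test): F1 %.2f, precision %.2f, recall %.2f, ROC-AUC %.2f\n",
      r$model_tag[i], r$f1[i], r$precision[i], r$recall[i], r$roc_auc[i]
    ))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf(
      "  Wilcoxon (%s vs %s): V = %g, p = %.3g over %d pairs\n",
      x$comparison$model_a, x$comparison$model_b,
      x$comparison$statistic, x$comparison$p_value, x$comparison$n_pairs
    ))
  }
  invisible(x)
}

#' @export
tidy.tof_experiment <- function(x, ...) {
  x$reports
}

#' @export
glance.tof_experiment <- function(x, ...) {
  te <- x$reports[x$reports$partition == "test", ]
  tibble::tibble(
    n_train = nrow(x$split$train),
    n_test = nrow(x$split$test),
    best_f1_test = max(te$f1),
    best_model = te$model_tag[which.max(te$f1)],
    wilcoxon_p = if (is.null(x$comparison)) NA_real_ else x$comparison$p_value,
    seed = x$seed
  )
}

#' Write an experiment report to JSON
#'
#' Serialises the split sizes, grid-search summaries, per-model evaluation
#' reports, learning curves and model comparison of a [run_experiment()]
#' result.
#'
#' @param experiment A `tof_experiment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(experiment, path) {
  stopifnot(inherits(experiment, "tof_experiment"))
  payload <- list(
    seed = experiment$seed,
    split = list(
      n_train = nrow(experiment$split$train),
      n_test = nrow(experiment$split$test),
      outliers_train = sum(as_label01(experiment$split$train$label)),
      outliers_test = sum(as_label01(experiment$split$test$label))
    ),
    grid_search = purrr::map(experiment$grid_search, function(g) {
      tidy(g)[, c("l2_lambda", "w_outlier", "mean_score", "best")]
    }),
    reports = experiment$reports,
    learning_curves = experiment$learning_curves,
    comparison = experiment$comparison
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
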