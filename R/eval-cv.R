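# Stratified k-fold machinery, grid search, repeated CV, learning curves.

#' Stratified k-fold assignment
#'
#' Assigns each row to one of `k` folds so that every class is spread as
#' evenly as possible: within each class, rows are shuffled and dealt
#' round-robin, so per-class fold counts differ by at most one (18 outliers
#' over 5 folds gives counts 4, 4, 4, 3, 3).
#'
#' @param y 0/1 or `"normal"`/`"outlier"` labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  k <- check_count(k, "k", 2L)
  y <- as_label01(y)
  if (min(table(y)) < k) {
    abort(sprintf(
      "Fewer minority-class rows (%d) than folds (%d); reduce k.",
      min(table(y)), k
    ))
  }
  folds <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

#' Default hyperparameter grid for CSLR
#'
#' Crosses the ridge strengths with the outlier-class weights. `"balanced"`
#' resolves to `n_normal / n_outlier` at fit time.
#'
#' @param l2_lambda Numeric vector of ridge penalties.
#' @param w_outlier Vector of outlier weights (numbers and/or `"balanced"`).
#' @return A tibble with columns `l2_lambda` and `w_outlier` (list column).
#' @export
cslr_grid <- function(l2_lambda = c(0.01, 0.1, 1, 10),
                      w_outlier = list(1, "balanced", 5, 10, 25)) {
  tidyr::expand_grid(l2_lambda = l2_lambda, w_outlier = as.list(w_outlier))
}

config_from_grid_row <- function(base_config, l2_lambda, w_outlier) {
  cslr_config(
    w_normal = base_config$w_normal,
    w_outlier = w_outlier,
    l2_lambda = l2_lambda,
    max_iter = base_config$max_iter,
    tol = base_config$tol,
    threshold = base_config$threshold,
    standardize = base_config$standardize
  )
}

score_fold <- function(train, test, features, config, cv_metric, label_col) {
  fit <- cslr_fit(train, features, config, label_col)
  truth <- as_label01(test[[label_col]])
  score <- predict_proba(fit, test)
  pred <- as.integer(score >= config$threshold)
  if (cv_metric == "roc_auc") {
    if (length(unique(truth)) < 2L) return(NA_real_)
    rank_auc(truth, score)
  } else {
    classification_metrics(truth, pred)[[cv_metric]]
  }
}

#' Grid search over CSLR hyperparameters by stratified k-fold CV
#'
#' For each grid point, fits on k-1 folds of the training table and scores
#' the held-out fold; the winning configuration maximises the mean fold
#' score. Ties are broken towards the more conservative model: larger
#' `l2_lambda`, then smaller outlier-to-normal weight ratio.
#'
#' @param train Training feature table (never the held-out test rows).
#' @param features Character vector of feature columns.
#' @param grid A [cslr_grid()]-style tibble.
#' @param k Number of folds.
#' @param cv_metric `"f1"` or `"roc_auc"`.
#' @param seed Integer seed for the folding.
#' @param base_config A [cslr_config()] supplying the non-searched settings.
#' @param label_col Label column name.
#' @return A list of class `tof_grid_search`: `results` (per-config mean and
#'   per-fold scores), `best_config` (a `cslr_config`), `cv_metric`, `folds`.
#' @export
grid_search_cv <- function(train, features, grid = cslr_grid(), k = 5L,
                           cv_metric = c("f1", "roc_auc"), seed = 1L,
                           base_config = cslr_config(), label_col = "label") {
  cv_metric <- match.arg(cv_metric)
  if (nrow(grid) == 0L) abort("Empty hyperparameter grid.")
  folds <- stratified_folds(train[[label_col]], k, seed)

  fold_scores <- purrr::map(seq_len(nrow(grid)), function(g) {
    cfg <- config_from_grid_row(base_config, grid$l2_lambda[g],
                                grid$w_outlier[[g]])
    vapply(seq_len(k), function(f) {
      score_fold(train[folds != f, ], train[folds == f, ],
                 features, cfg, cv_metric, label_col)
    }, numeric(1))
  })

  results <- grid
  results$fold_scores <- fold_scores
  results$mean_score <- vapply(fold_scores, function(s) mean(s, na.rm = TRUE),
                               numeric(1))
  results$weight_ratio <- vapply(seq_len(nrow(grid)), function(g) {
    w <- grid$w_outlier[[g]]
    if (identical(w, "balanced")) {
      sum(as_label01(train[[label_col]]) == 0) /
        sum(as_label01(train[[label_col]]) == 1)
    } else {
      as.numeric(w)
    }
  }, numeric(1)) / base_config$w_normal

  ord <- order(-results$mean_score, -results$l2_lambda, results$weight_ratio)
  best_row <- ord[1]
  best_config <- config_from_grid_row(base_config, results$l2_lambda[best_row],
                                      results$w_outlier[[best_row]])

  structure(
    list(
      results = results,
      best_row = best_row,
      best_config = best_config,
      cv_metric = cv_metric,
      folds = folds,
      k = k,
      seed = seed
    ),
    class = "tof_grid_search"
  )
}

#' @export
print.tof_grid_search <- function(x, ...) {
  b <- x$results[x$best_row, ]
  cat(sprintf(
    "<tof_grid_search> %d configs x %d folds (metric: %s)\n",
    nrow(x$results), x$k, x$cv_metric
  ))
  cat(sprintf(
    "  best: lambda = %g, w_outlier = %s (mean %s = %.3f)\n",
    b$l2_lambda, format(b$w_outlier[[1]]), x$cv_metric, b$mean_score
  ))
  invisible(x)
}

#' @export
tidy.tof_grid_search <- function(x, ...) {
  res <- x$results
  tibble::tibble(
    l2_lambda = res$l2_lambda,
    w_outlier = vapply(res$w_outlier, format, character(1)),
    weight_ratio = res$weight_ratio,
    mean_score = res$mean_score,
    fold_scores = res$fold_scores,
    best = seq_len(nrow(res)) == x$best_row
  )
}

#' Paired per-fold scores from repeated stratified cross-validation
#'
#' Runs `times` rounds of stratified k-fold CV on the training table with
#' shared fold assignments per round, fitting both feature sets on identical
#' folds, and returns the paired held-out fold scores. This supplies the
#' paired samples for [compare_models()].
#'
#' @param train Training feature table.
#' @param features_a,features_b The two feature sets to compare.
#' @param config_a,config_b Fitted-model configurations for each set.
#' @param k Folds per round; `times` rounds gives `k * times` pairs.
#' @param times Number of CV repetitions.
#' @param metric `"f1"` or `"roc_auc"`.
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return A tibble with columns `round`, `fold`, `score_a`, `score_b`.
#' @export
repeated_cv_scores <- function(train, features_a, features_b,
                               config_a, config_b, k = 5L, times = 5L,
                               metric = "f1", seed = 1L, label_col = "label") {
  purrr::map(seq_len(times), function(r) {
    folds <- stratified_folds(train[[label_col]], k,
                              derive_seed(seed, paste0("repcv", r)))
    purrr::map(seq_len(k), function(f) {
      tr <- train[folds != f, ]
      te <- train[folds == f, ]
      tibble::tibble(
        round = r, fold = f,
        score_a = score_fold(tr, te, features_a, config_a, metric, label_col),
        score_b = score_fold(tr, te, features_b, config_b, metric, label_col)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Learning curves for a CSLR configuration
#'
#' For each training-set size, draws a stratified subsample of the training
#' table, runs stratified k-fold CV, and records mean and SD of F1 and
#' ROC-AUC on both the fitting folds (training score) and the held-out folds
#' (validation score). Sizes too small to leave at least one outlier per fold
#' are skipped with a warning.
#'
#' @param train Training feature table.
#' @param features Feature column names.
#' @param config A [cslr_config()] (typically the grid-search winner).
#' @param train_sizes Integer vector of subsample sizes.
#' @param k Folds.
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return A tibble of class `tof_learning_curves`: one row per size x
#'   partition (train/validation) x metric, with `mean_score` and `sd_score`.
#' @export
learning_curves <- function(train, features, config,
                            train_sizes = NULL, k = 5L, seed = 1L,
                            label_col = "label") {
  y <- as_label01(train[[label_col]])
  n <- length(y)
  if (is.null(train_sizes)) {
    train_sizes <- unique(round(seq(0.3, 1, by = 0.175) * n))
  }
  rows <- purrr::map(train_sizes, function(sz) {
    sub_idx <- with_seed(derive_seed(seed, paste0("lc", sz)), {
      if (sz >= n) {
        seq_len(n)
      } else {
        per_class <- largest_remainder(table(y), sz, cap = table(y))
        c(
          sample(which(y == 0), per_class[1]),
          sample(which(y == 1), per_class[2])
        )
      }
    })
    sub <- train[sub_idx, ]
    n_out <- sum(as_label01(sub[[label_col]]))
    if (n_out < k) {
      warn(sprintf("Skipping size %d: only %d outliers for %d folds.",
                   sz, n_out, k))
      return(NULL)
    }
    folds <- stratified_folds(sub[[label_col]], k, derive_seed(seed, "lcfold"))
    per_fold <- purrr::map(seq_len(k), function(f) {
      tr <- sub[folds != f, ]
      te <- sub[folds == f, ]
      fit <- cslr_fit(tr, features, config, label_col)
      score_of <- function(d) {
        truth <- as_label01(d[[label_col]])
        s <- predict_proba(fit, d)
        p <- as.integer(s >= config$threshold)
        c(
          f1 = classification_metrics(truth, p)$f1,
          roc_auc = if (length(unique(truth)) > 1L) rank_auc(truth, s) else NA_real_
        )
      }
      list(train = score_of(tr), validation = score_of(te))
    })
    purrr::map(c("train", "validation"), function(part) {
      sc <- do.call(rbind, purrr::map(per_fold, part))
      tibble::tibble(
        size = sz, partition = part,
        metric = colnames(sc),
        mean_score = colMeans(sc, na.rm = TRUE),
        sd_score = apply(sc, 2, sd, na.rm = TRUE)
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tof_learning_curves", class(out))
  out
}
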