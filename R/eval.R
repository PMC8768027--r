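# Evaluation protocol: stratified splitting, imbalance-aware metrics,
# rank-based ROC analysis, bootstrap intervals, paired model comparison.

#' Stratified train/test split
#'
#' Holds out `ceiling(n * test_fraction)` rows as a test set. Under
#' stratification the per-class test counts are allocated proportionally with
#' largest-remainder rounding, so the class imbalance of the full table is
#' preserved in both partitions; which rows fill each class quota is drawn
#' uniformly, deterministically given `seed`. Splitting 533 rows with 30
#' positives at `test_fraction = 0.4` gives a 214-row test set with 12
#' positives and a 319-row training set with 18.
#'
#' @param data Data frame with a label column.
#' @param test_fraction Fraction of rows held out, in (0, 1).
#' @param stratified Preserve per-class proportions (default) or split
#'   completely at random.
#' @param seed Integer seed.
#' @param label_col Name of the label column.
#' @return A list of class `tof_split` with tibbles `train` and `test` and the
#'   0/1 `test_index` used.
#' @examples
#' d <- tibble::tibble(label = rep(c("outlier", "normal"), c(30, 503)))
#' sp <- stratified_split(d, test_fraction = 0.4, seed = 1)
#' nrow(sp$test); sum(sp$test$label == "outlier")
#' @export
stratified_split <- function(data, test_fraction = 0.4, stratified = TRUE,
                             seed = 1L, label_col = "label") {
  test_fraction <- check_fraction(test_fraction, "test_fraction")
  y <- as_label01(data[[label_col]])
  n <- length(y)
  counts <- c(`0` = sum(y == 0), `1` = sum(y == 1))
  if (any(counts < 2L)) abort("Each class needs at least 2 members to split.")
  n_test <- as.integer(ceiling(n * test_fraction))

  test_idx <- with_seed(derive_seed(seed, "split"), {
    if (stratified) {
      per_class <- largest_remainder(counts, n_test, cap = counts)
      c(
        sample(which(y == 0), per_class[1]),
        sample(which(y == 1), per_class[2])
      )
    } else {
      sample(n, n_test)
    }
  })
  in_test <- seq_len(n) %in% test_idx
  structure(
    list(
      train = tibble::as_tibble(data[!in_test, ]),
      test = tibble::as_tibble(data[in_test, ]),
      test_index = which(in_test),
      test_fraction = test_fraction,
      stratified = stratified,
      seed = seed
    ),
    class = "tof_split"
  )
}

# Rank (Mann-Whitney) AUC with ties contributing 1/2.
rank_auc <- function(y_true, y_score) {
  pos <- y_true == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("ROC-AUC needs both classes in y_true.")
  r <- rank(y_score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for imbalanced outlier detection
#'
#' Computes the confusion counts and the precision, recall and F1 score
#' (the metrics of choice under heavy class imbalance), plus the rank-based
#' (Mann-Whitney) ROC-AUC when continuous scores are supplied. Zero-division
#' conventions: precision = 0 when nothing is predicted positive; F1 = 0 when
#' precision + recall = 0.
#'
#' @param y_true 0/1 (or `"normal"`/`"outlier"`) true labels.
#' @param y_pred 0/1 predicted labels.
#' @param y_score Optional continuous scores for ROC-AUC (ties count 1/2).
#' @return A one-row tibble: `tp, fp, fn, tn, precision, recall, f1, roc_auc,
#'   n, n_outliers`.
#' @examples
#' # 12 true outliers, 9 detected with no false alarms:
#' truth <- rep(c(1, 0), c(12, 202))
#' pred <- rep(c(1, 0, 0), c(9, 3, 202))
#' classification_metrics(truth, pred)
#' @export
classification_metrics <- function(y_true, y_pred, y_score = NULL) {
  y_true <- as_label01(y_true)
  y_pred <- as_label01(y_pred)
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  auc <- if (!is.null(y_score)) rank_auc(y_true, y_score) else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1, roc_auc = auc,
    n = length(y_true), n_outliers = sum(y_true)
  )
}

#' Receiver-operating-characteristic curve
#'
#' Enumerates every distinct score threshold and returns the operating points
#' (FPR, TPR), monotone non-decreasing in both coordinates with endpoints
#' (0, 0) and (1, 1). The trapezoidal area under the returned curve equals
#' the rank-based AUC (ties handled as 1/2) to floating precision.
#'
#' @inheritParams classification_metrics
#' @return A tibble of class `tof_roc` with columns `threshold`, `fpr`,
#'   `tpr`; attribute `auc` holds the trapezoidal area.
#' @export
roc_curve <- function(y_true, y_score) {
  y_true <- as_label01(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) abort("ROC needs both classes in y_true.")
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_score[ord]
  yt <- y_true[ord]
  # one operating point after each block of tied scores
  block_end <- which(c(diff(ys) != 0, TRUE))
  tp <- cumsum(yt)[block_end]
  fp <- cumsum(1 - yt)[block_end]
  out <- tibble::tibble(
    threshold = c(Inf, ys[block_end]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("tof_roc", class(out))
  out
}

#' Stratified percentile bootstrap confidence interval for a metric
#'
#' Resamples the evaluation rows with replacement within each true class
#' (keeping the class mix fixed), recomputes the metric per replicate, and
#' returns the 2.5th/97.5th percentile interval. Replicates on which the
#' metric is undefined are dropped and counted.
#'
#' @inheritParams classification_metrics
#' @param metric One of `"f1"`, `"precision"`, `"recall"`, `"roc_auc"`.
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `metric, estimate, low, high, reps_used,
#'   reps_dropped`.
#' @export
bootstrap_ci <- function(y_true, y_pred = NULL, y_score = NULL,
                         metric = c("f1", "precision", "recall", "roc_auc"),
                         reps = 1000L, seed = 1L, conf = 0.95) {
  metric <- match.arg(metric)
  reps <- check_count(reps, "reps", 100L)
  y_true <- as_label01(y_true)
  if (metric == "roc_auc" && is.null(y_score)) {
    abort("`y_score` is required for roc_auc.")
  }
  if (metric != "roc_auc" && is.null(y_pred)) {
    abort(sprintf("`y_pred` is required for %s.", metric))
  }

  eval_metric <- function(idx) {
    yt <- y_true[idx]
    if (metric == "roc_auc") {
      if (length(unique(yt)) < 2L) return(NA_real_)
      rank_auc(yt, y_score[idx])
    } else {
      m <- classification_metrics(yt, y_pred[idx])
      m[[metric]]
    }
  }
  point <- eval_metric(seq_along(y_true))

  cls <- split(seq_along(y_true), y_true)
  vals <- with_seed(derive_seed(seed, paste0("bootstrap_", metric)), {
    vapply(seq_len(reps), function(r) {
      idx <- unlist(lapply(cls, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      eval_metric(idx)
    }, numeric(1))
  })
  ok <- vals[!is.na(vals)]
  if (!length(ok)) abort("Metric undefined on every bootstrap replicate.")
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(
    metric = metric, estimate = point, low = qs[1], high = qs[2],
    reps_used = length(ok), reps_dropped = reps - length(ok)
  )
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Compares paired performance scores (e.g. per-fold F1 of two models sharing
#' the same cross-validation folds) with the two-sided Wilcoxon signed-rank
#' test. Zero differences are dropped; the null distribution is exact for up
#' to 25 informative pairs without ties in the absolute differences, and a
#' normal approximation with tie correction otherwise. If every difference is
#' zero the comparison is degenerate and `p_value = 1`.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of paired scores.
#' @return A one-row tibble: `statistic` (V, the positive-rank sum for
#'   a - b), `p_value`, `n_pairs` (informative pairs), `exact`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) abort("Paired scores differ in length.")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_pairs = 0L,
                          exact = TRUE))
  }
  has_ties <- anyDuplicated(abs(d)) > 0
  use_exact <- n <= 25L && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_pairs = n,
    exact = use_exact
  )
}
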