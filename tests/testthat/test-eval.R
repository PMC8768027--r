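# Evaluation protocol: splitting, metrics, ROC, CV, bootstrap, Wilcoxon.

test_that("stratified_split reproduces the cohort partition arithmetic", {
  d <- tibble::tibble(label = rep(c("outlier", "normal"), c(30, 503)))
  sp <- stratified_split(d, test_fraction = 0.4, seed = 1)
  expect_equal(nrow(sp$test), 214L)
  expect_equal(sum(sp$test$label == "outlier"), 12L)
  expect_equal(nrow(sp$train), 319L)
  expect_equal(sum(sp$train$label == "outlier"), 18L)

  # size contract and conservation over random tables; per-class test counts
  # within one unit of the proportional quota (counting oracle)
  set.seed(10)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    npos <- sample(5:20, 1)
    frac <- runif(1, 0.2, 0.6)
    d2 <- tibble::tibble(label = sample(rep(c(1, 0), c(npos, n - npos))))
    sp2 <- stratified_split(d2, frac, seed = i)
    expect_equal(nrow(sp2$test), ceiling(n * frac))
    expect_equal(nrow(sp2$test) + nrow(sp2$train), n)
    expect_equal(sum(sp2$test$label) + sum(sp2$train$label), npos)
    expect_lte(abs(sum(sp2$test$label) - npos * frac), 1)
  }

  expect_error(stratified_split(tibble::tibble(label = c(1, 0, 0)), 0.4),
               "at least 2")
})

test_that("metrics reproduce the worked confusion examples", {
  # 12 outliers, 9 detected, 0 false alarms
  truth <- rep(c(1, 0), c(12, 202))
  pred <- rep(c(1, 0, 0), c(9, 3, 202))
  m <- classification_metrics(truth, pred)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 18 / 21, tolerance = 1e-12)
  expect_equal(round(m$f1, 2), 0.86)

  # 12 outliers, 4 detected, 12 false alarms
  truth2 <- rep(c(1, 0), c(12, 202))
  pred2 <- c(rep(1, 4), rep(0, 8), rep(1, 12), rep(0, 190))
  m2 <- classification_metrics(truth2, pred2)
  expect_equal(m2$precision, 0.25)
  expect_equal(m2$recall, 1 / 3, tolerance = 1e-12)
  expect_equal(m2$f1, 8 / 28, tolerance = 1e-12)
  expect_equal(round(m2$f1, 2), 0.29)

  # zero-division conventions
  m0 <- classification_metrics(c(1, 0), c(0, 0))
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)

  # degenerate ROC cases
  expect_equal(classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                      c(0.9, 0.8, 0.2, 0.1))$roc_auc, 1)
  expect_equal(classification_metrics(c(1, 0), c(0, 0), c(0.5, 0.5))$roc_auc, 0.5)
})

test_that("roc_curve agrees with exhaustive threshold enumeration", {
  y <- c(1, 0, 1, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  rc <- roc_curve(y, s)
  # oracle: enumerate all distinct thresholds
  thr <- sort(unique(s), decreasing = TRUE)
  oracle <- t(vapply(thr, function(th) {
    c(fpr = sum(y == 0 & s >= th) / sum(y == 0),
      tpr = sum(y == 1 & s >= th) / sum(y == 1))
  }, numeric(2)))
  expect_equal(rc$fpr, c(0, oracle[, "fpr"]))
  expect_equal(rc$tpr, c(0, oracle[, "tpr"]))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)

  # scores equal to labels pass through (0, 1)
  rc2 <- roc_curve(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_true(any(rc2$fpr == 0 & rc2$tpr == 1))

  # reversing scores maps AUC -> 1 - AUC; trapezoid equals rank AUC to 1e-12
  set.seed(14)
  for (i in 1:6) {
    n <- 30
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2) # ties on purpose
    a1 <- attr(roc_curve(y, s), "auc")
    expect_equal(a1, tofanomaly:::rank_auc(y, s), tolerance = 1e-12)
    expect_equal(attr(roc_curve(y, -s), "auc"), 1 - a1, tolerance = 1e-12)
  }
})

test_that("stratified folds spread the minority class evenly", {
  y <- rep(c(1, 0), c(18, 301))
  folds <- stratified_folds(y, k = 5, seed = 2)
  expect_equal(sort(table(folds[y == 1])), sort(c(4, 4, 4, 3, 3)),
               ignore_attr = TRUE)
  expect_equal(length(folds), 319L)
  expect_error(stratified_folds(rep(c(1, 0), c(3, 50)), k = 5), "reduce k")
})

test_that("grid search selects by mean fold score with conservative ties", {
  d <- toy_feature_table(n = 160, n_pos = 20, seed = 21)
  g1 <- grid_search_cv(d, c("f_a", "f_b"),
                       grid = tibble::tibble(l2_lambda = 0.5, w_outlier = list(5)),
                       k = 4, seed = 3)
  expect_equal(g1$best_config$l2_lambda, 0.5)
  expect_equal(g1$best_config$w_outlier, 5)

  gs <- grid_search_cv(d, c("f_a", "f_b"), grid = cslr_grid(), k = 4, seed = 3)
  expect_equal(max(gs$results$mean_score),
               gs$results$mean_score[gs$best_row])
  # tie-break: among top-scoring rows, the chosen one has the largest
  # l2_lambda, then the smallest weight ratio
  top <- which(gs$results$mean_score == max(gs$results$mean_score))
  if (length(top) > 1) {
    expect_equal(gs$results$l2_lambda[gs$best_row],
                 max(gs$results$l2_lambda[top]))
  }
  expect_s3_class(tidy(gs), "tbl_df")
})

test_that("bootstrap intervals behave on degenerate and tiny inputs", {
  # perfect constant predictions -> interval (1, 1)
  ci <- bootstrap_ci(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(10, 40)),
                     metric = "f1", reps = 200, seed = 1)
  expect_equal(ci$low, 1)
  expect_equal(ci$high, 1)

  # interval contains the point estimate for a well-behaved metric
  set.seed(3)
  y <- rep(c(1, 0), c(15, 85))
  pred <- ifelse(runif(100) < 0.2, 1 - y, y)
  ci2 <- bootstrap_ci(y, pred, metric = "f1", reps = 500, seed = 2)
  expect_lte(ci2$low, ci2$estimate)
  expect_gte(ci2$high, ci2$estimate)

  # n = 4 stratified resampling: every replicate recall lies in the
  # exhaustively enumerable support {0, 1/2, 1}
  y4 <- c(1, 1, 0, 0)
  p4 <- c(1, 0, 0, 1)
  ci3 <- bootstrap_ci(y4, p4, metric = "recall", reps = 400, seed = 4)
  support <- c(0, 0.5, 1)
  expect_true(ci3$low %in% support || ci3$low > 0 && ci3$low < 1)
  expect_true(ci3$low <= ci3$high)
  # exact enumeration: resampling 2 positives with replacement from
  # {caught, missed} gives recall 0, 1/2, 1 with probs 1/4, 1/2, 1/4
  expect_equal(ci3$estimate, 0.5)
  expect_equal(ci3$low, 0)
  expect_equal(ci3$high, 1)

  expect_error(bootstrap_ci(y4, p4, metric = "f1", reps = 10), ">= 100")
})

test_that("compare_models matches exact sign-assignment enumeration", {
  # identical scores -> degenerate p = 1
  expect_equal(compare_models(1:5, 1:5)$p_value, 1)

  # n = 6 all-positive differences: V = 21, exact two-sided p = 2/64
  res <- compare_models(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6) - (1:6) / 100)
  d <- c(2, 3, 4, 5, 6, 7) - (c(1, 2, 3, 4, 5, 6) - (1:6) / 100)
  expect_true(all(d > 0))
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)

  # swapping the inputs leaves p unchanged
  set.seed(15)
  a <- rnorm(10)
  b <- rnorm(10)
  expect_equal(compare_models(a, b)$p_value, compare_models(b, a)$p_value)

  # brute-force enumeration oracle for n <= 12 without ties
  for (n in c(5, 8, 11)) {
    a <- rnorm(n)
    b <- rnorm(n)
    d <- a - b
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    # enumerate all 2^n sign assignments of the ranks
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% r
    p_exact <- min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
    res <- compare_models(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, p_exact, tolerance = 1e-10)
  }
})

test_that("learning curves cover feasible sizes and flag overfitting", {
  d <- toy_feature_table(n = 200, n_pos = 25, seed = 30)
  lc <- learning_curves(d, c("f_a", "f_b", "f_c"),
                        cslr_config(w_outlier = 5, l2_lambda = 0.1),
                        train_sizes = c(80, 140, 200), k = 4, seed = 5)
  expect_s3_class(lc, "tof_learning_curves")
  expect_setequal(unique(lc$size), c(80, 140, 200))
  expect_setequal(unique(lc$partition), c("train", "validation"))
  # training score does not improve with more data (overfitting signature)
  tr_f1 <- lc[lc$partition == "train" & lc$metric == "f1", ]
  expect_gte(tr_f1$mean_score[tr_f1$size == 80],
             tr_f1$mean_score[tr_f1$size == 200] - 0.05)
  # infeasible size skipped with a warning
  expect_warning(
    lc2 <- learning_curves(d, c("f_a", "f_b"), cslr_config(),
                           train_sizes = c(20, 150), k = 4, seed = 5),
    "Skipping"
  )
  expect_setequal(unique(lc2$size), 150)
})

test_that("run_experiment keeps CV hygiene and is reproducible", {
  co <- default_cohort()
  ex <- run_experiment(co$features, seed = 42, with_ci = FALSE,
                       with_learning_curves = FALSE, with_comparison = FALSE)
  rep <- ex$reports

  # identical partitions for both models
  expect_equal(nrow(ex$split$train) + nrow(ex$split$test), 533L)
  expect_equal(unique(rep$n[rep$partition == "test"]), 214L)
  expect_equal(unique(rep$n_outliers[rep$partition == "test"]), 12L)

  # the headline ordering: engineered beats basic on held-out F1
  f1 <- function(tag) rep$f1[rep$model_tag == tag & rep$partition == "test"]
  expect_gt(f1("engineered"), f1("basic"))

  # determinism at a smaller problem size
  small <- build_feature_table(simulate_dataset(small_config(seed = 4)))
  e1 <- run_experiment(small, seed = 5, k = 3,
                       grid = tibble::tibble(l2_lambda = c(0.1, 1),
                                             w_outlier = list(5, 5)),
                       with_ci = FALSE, with_learning_curves = FALSE,
                       with_comparison = FALSE)
  e2 <- run_experiment(small, seed = 5, k = 3,
                       grid = tibble::tibble(l2_lambda = c(0.1, 1),
                                             w_outlier = list(5, 5)),
                       with_ci = FALSE, with_learning_curves = FALSE,
                       with_comparison = FALSE)
  expect_identical(e1$reports, e2$reports)
})
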