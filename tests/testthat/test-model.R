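# Cost-sensitive logistic regression.

test_that("cslr_objective matches closed forms and a brute-force oracle", {
  set.seed(5)
  x <- matrix(rnorm(40), nrow = 10)
  y <- rep(c(1, 0), c(3, 7))

  # beta = 0 with unit weights -> n log 2
  expect_equal(cslr_objective(rep(0, 4), 0, x, y), 10 * log(2), tolerance = 1e-12)

  # doubling both class weights doubles the unpenalised term
  beta <- rnorm(4)
  j1 <- cslr_objective(beta, 0.3, x, y, w_normal = 1, w_outlier = 2)
  j2 <- cslr_objective(beta, 0.3, x, y, w_normal = 2, w_outlier = 4)
  expect_equal(j2, 2 * j1, tolerance = 1e-10)

  # brute-force per-sample summation oracle, with penalty
  wn <- 1.5
  wo <- 4
  lam <- 0.7
  b0 <- -0.2
  oracle <- sum(vapply(seq_len(10), function(i) {
    p <- 1 / (1 + exp(-(sum(beta * x[i, ]) + b0)))
    w <- if (y[i] == 1) wo else wn
    -w * (y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }, numeric(1))) + lam * sum(beta^2)
  expect_equal(cslr_objective(beta, b0, x, y, wn, wo, lam), oracle,
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(6)
  for (rep in 1:4) {
    n <- 12
    p <- 3
    x <- matrix(rnorm(n * p), n)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    beta <- rnorm(p) * 0.5
    b0 <- rnorm(1) * 0.3
    g <- tofanomaly:::cslr_gradient(beta, b0, x, y, 1.3, 3, 0.4)
    h <- 1e-6
    fd <- vapply(seq_len(p + 1), function(j) {
      e <- numeric(p + 1)
      e[j] <- h
      up <- cslr_objective(beta + e[-1], b0 + e[1], x, y, 1.3, 3, 0.4)
      dn <- cslr_objective(beta - e[-1], b0 - e[1], x, y, 1.3, 3, 0.4)
      (up - dn) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("equal-weight fit reduces to a reference ridge logistic regression", {
  skip_if_not_installed("glmnet")
  d <- toy_feature_table(n = 200, n_pos = 60, seed = 3)
  lam <- 2
  fit <- cslr_fit(d, c("f_a", "f_b", "f_c"),
                  cslr_config(w_outlier = 1, l2_lambda = lam,
                              standardize = FALSE, tol = 1e-12))
  y <- as.integer(d$label == "outlier")
  x <- as.matrix(d[, c("f_a", "f_b", "f_c")])
  # glmnet ridge: (1/n) nll + lambda_g/2 ||b||^2  <=>  lambda_g = 2 lam / n
  ref <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 2 * lam / nrow(d), standardize = FALSE,
                        thresh = 1e-14)
  expect_equal(unname(fit$beta), as.numeric(ref$beta), tolerance = 1e-3)
  expect_equal(fit$beta0, as.numeric(ref$a0), tolerance = 1e-3)
})

test_that("heavy regularisation collapses to the intercept-only model", {
  d <- toy_feature_table(n = 150, n_pos = 30, seed = 4)
  fit <- cslr_fit(d, c("f_a", "f_b", "f_c"),
                  cslr_config(l2_lambda = 1e7))
  expect_lt(sqrt(sum(fit$beta^2)), 1e-3)
  prev <- mean(d$label == "outlier")
  pr <- predict_proba(fit, d)
  expect_equal(mean(pr), prev, tolerance = 1e-3)
  expect_lt(max(pr) - min(pr), 1e-3)
})

test_that("fit recovers the generating coefficients on simulated data", {
  set.seed(77)
  n <- 5000
  beta_true <- c(1.5, -2, 0, 0.5)
  x <- matrix(rnorm(n * 4), n)
  p <- stats::plogis(drop(x %*% beta_true))
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- paste0("x", 1:4)
  d$label <- rbinom(n, 1, p)
  fit <- cslr_fit(d, paste0("x", 1:4),
                  cslr_config(l2_lambda = 1e-6, standardize = FALSE))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), beta_true, tolerance = 0.15)
})

test_that("the accepted objective trace is monotone non-increasing", {
  d <- toy_feature_table(n = 120, n_pos = 15, seed = 9)
  fit <- cslr_fit(d, c("f_a", "f_b", "f_c"),
                  cslr_config(w_outlier = 8, l2_lambda = 0.05))
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_true(fit$converged)
})

test_that("predictions follow the logistic link and threshold convention", {
  d <- toy_feature_table(n = 60, n_pos = 10, seed = 2)
  fit <- cslr_fit(d, c("f_a", "f_b"), cslr_config())

  # hand-set model: beta = 1, beta0 = 0, identity scaler
  fit$beta <- c(f_a = 1, f_b = 0)
  fit$beta0 <- 0
  fit$scaler$center[] <- 0
  fit$scaler$scale[] <- 1
  nd <- tibble::tibble(f_a = c(0.5, stats::qlogis(c(0.49, 0.5, 0.51))), f_b = 0)
  pr <- predict_proba(fit, nd)
  expect_equal(pr[1], 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  # boundary convention: probability >= threshold -> class 1
  expect_equal(classify(fit, nd[2:4, ], threshold = 0.5), c(0L, 1L, 1L))
  # compositional oracle
  expect_identical(classify(fit, nd), as.integer(predict_proba(fit, nd) >= 0.5))

  # very large intercept saturates
  fit$beta0 <- 50
  expect_true(all(predict_proba(fit, nd) > 0.999))

  expect_error(predict_proba(fit, tibble::tibble(f_a = 1)), "Missing")
})

test_that("raising the outlier weight does not reduce training recall", {
  d <- toy_feature_table(n = 150, n_pos = 12, seed = 12)
  recalls <- vapply(c(1, 5, 15), function(w) {
    fit <- cslr_fit(d, c("f_a", "f_b", "f_c"),
                    cslr_config(w_outlier = w, l2_lambda = 0.1))
    pred <- classify(fit, d)
    m <- classification_metrics(as.integer(d$label == "outlier"), pred)
    m$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("fit validates its inputs", {
  d <- toy_feature_table()
  d1 <- d
  d1$label <- "normal"
  expect_error(cslr_fit(d1, c("f_a", "f_b")), "Both classes")
  d2 <- d
  d2$f_a[3] <- NA
  expect_error(cslr_fit(d2, c("f_a", "f_b")), "Non-finite")
  expect_error(cslr_config(w_outlier = -1), "positive")
  expect_error(cslr_config(threshold = 1.2), "between 0 and 1")
})

test_that("fitted models serialise to JSON and back", {
  d <- toy_feature_table(n = 100, n_pos = 15, seed = 6)
  fit <- cslr_fit(d, c("f_a", "f_b", "f_c"),
                  cslr_config(w_outlier = 5, l2_lambda = 0.3))
  path <- withr::local_tempfile(fileext = ".json")
  write_cslr(fit, path)
  back <- read_cslr(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$beta0, fit$beta0)
  expect_equal(back$scaler, fit$scaler)
  expect_equal(predict_proba(back, d), predict_proba(fit, d), tolerance = 1e-12)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4L)
  expect_equal(glance(fit)$n, 100L)
})
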