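# Cost-sensitive L2-regularised logistic regression (CSLR).
#
# The objective is the class-weighted penalised negative log-likelihood
#   J(b0, b) = sum_i w_{y_i} [ -y_i log p_i - (1 - y_i) log(1 - p_i) ]
#              + lambda * ||b||^2 ,   p_i = plogis(b0 + x_i' b),
# with the intercept excluded from the penalty. Weighting the rare-class
# terms more heavily penalises errors on outliers more than errors on the
# normal class, which is what makes plain logistic regression usable under
# ~5% positive prevalence.

PROB_EPS <- 1e-12

#' Configuration for cost-sensitive logistic regression
#'
#' @param w_normal,w_outlier Positive error weights for the normal (y = 0)
#'   and outlier (y = 1) class. `w_outlier = "balanced"` sets it to
#'   `n_normal / n_outlier` at fit time, so both classes contribute equal
#'   total weight.
#' @param l2_lambda Ridge penalty strength on the coefficients (not the
#'   intercept), `>= 0`.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence tolerance on the absolute change of the objective.
#' @param threshold Decision cutoff on the predicted outlier probability;
#'   class weights, not the threshold, carry the cost asymmetry, so the
#'   default stays at 0.5.
#' @param standardize Z-score the features using training statistics before
#'   fitting (the features span about three orders of magnitude, so this is
#'   on by default).
#' @return A list of class `cslr_config`.
#' @export
cslr_config <- function(w_normal = 1, w_outlier = 1, l2_lambda = 0.1,
                        max_iter = 1000L, tol = 1e-8, threshold = 0.5,
                        standardize = TRUE) {
  if (!identical(w_outlier, "balanced")) {
    w_outlier <- check_positive(w_outlier, "w_outlier")
  }
  structure(
    list(
      w_normal = check_positive(w_normal, "w_normal"),
      w_outlier = w_outlier,
      l2_lambda = check_nonneg(l2_lambda, "l2_lambda"),
      max_iter = check_count(max_iter, "max_iter", 1L),
      tol = check_positive(tol, "tol"),
      threshold = check_fraction(threshold, "threshold"),
      standardize = isTRUE(standardize)
    ),
    class = "cslr_config"
  )
}

as_label01 <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("normal", "outlier"))
    if (length(bad)) abort("Labels must be 'normal'/'outlier' or 0/1.")
    return(as.integer(y == "outlier"))
  }
  if (!all(y %in% c(0, 1))) abort("Numeric labels must be 0/1.")
  as.integer(y)
}

feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    abort(sprintf("Missing feature columns: %s", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("Non-finite feature values.")
  x
}

#' Weighted penalised negative log-likelihood of a CSLR model
#'
#' @param beta Coefficient vector (one per feature column of `x`).
#' @param beta0 Intercept.
#' @param x Numeric feature matrix (rows = observations).
#' @param y 0/1 labels (1 = outlier).
#' @param w_normal,w_outlier Class error weights.
#' @param l2_lambda Ridge penalty on `beta` (intercept unpenalised).
#' @return The scalar objective value. Probabilities are clipped to
#'   `[1e-12, 1 - 1e-12]` inside the logs.
#' @export
cslr_objective <- function(beta, beta0, x, y, w_normal = 1, w_outlier = 1,
                           l2_lambda = 0) {
  if (nrow(x) != length(y)) abort("`x` rows and `y` length differ.")
  y <- as_label01(y)
  eta <- drop(x %*% beta) + beta0
  p <- pmin(pmax(stats::plogis(eta), PROB_EPS), 1 - PROB_EPS)
  w <- ifelse(y == 1, w_outlier, w_normal)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) + l2_lambda * sum(beta^2)
}

# Analytic gradient of cslr_objective w.r.t. c(beta0, beta).
cslr_gradient <- function(beta, beta0, x, y, w_normal = 1, w_outlier = 1,
                          l2_lambda = 0) {
  p <- stats::plogis(drop(x %*% beta) + beta0)
  w <- ifelse(y == 1, w_outlier, w_normal)
  r <- w * (p - y)
  c(sum(r), drop(crossprod(x, r)) + 2 * l2_lambda * beta)
}

# Damped-Newton minimiser with Armijo backtracking: the objective is convex,
# so the Newton direction with a line search gives monotone decrease and
# quadratic terminal convergence.
cslr_optimise <- function(x, y, w_normal, w_outlier, l2_lambda,
                          max_iter, tol) {
  p_dim <- ncol(x)
  beta <- numeric(p_dim)
  beta0 <- 0
  obj <- cslr_objective(beta, beta0, x, y, w_normal, w_outlier, l2_lambda)
  trace <- obj
  converged <- FALSE
  w <- ifelse(y == 1, w_outlier, w_normal)
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta) + beta0
    pr <- stats::plogis(eta)
    g <- cslr_gradient(beta, beta0, x, y, w_normal, w_outlier, l2_lambda)
    wt <- pmax(w * pr * (1 - pr), 1e-10)
    xa <- cbind(1, x)
    h <- crossprod(xa * sqrt(wt))
    diag(h)[-1] <- diag(h)[-1] + 2 * l2_lambda
    step <- tryCatch(
      -solve(h, g),
      error = function(e) -g / sqrt(sum(g^2) + 1e-12)
    )
    # Armijo backtracking on the full objective
    alpha <- 1
    repeat {
      cand0 <- beta0 + alpha * step[1]
      cand <- beta + alpha * step[-1]
      new_obj <- cslr_objective(cand, cand0, x, y, w_normal, w_outlier, l2_lambda)
      if (new_obj <= obj + 1e-4 * alpha * sum(g * step) || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    if (new_obj > obj) break # no descent possible at machine precision
    delta <- obj - new_obj
    beta0 <- cand0
    beta <- cand
    obj <- new_obj
    trace <- c(trace, obj)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = unname(beta), beta0 = unname(beta0), objective = obj,
       trace = trace, converged = converged, iterations = length(trace) - 1L)
}

#' Fit a cost-sensitive logistic regression
#'
#' Minimises the class-weighted penalised negative log-likelihood (see
#' [cslr_objective()]) by damped Newton iteration with backtracking line
#' search, starting from zero coefficients, until the objective change drops
#' below `config$tol` or `config$max_iter` is reached. When
#' `config$standardize` is on, features are z-scored with training-set
#' statistics that are stored on the model and re-applied at prediction time.
#'
#' @param data A data frame containing the feature columns and a label column
#'   (`"normal"`/`"outlier"` strings or 0/1).
#' @param features Character vector of feature column names; defaults to the
#'   full 15-feature set ([all_features()]).
#' @param config A [cslr_config()].
#' @param label_col Name of the label column.
#' @return An object of class `cslr_fit`: coefficients, intercept, per-feature
#'   scaler, resolved config, convergence flag, final objective, and the
#'   objective trace.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(a = rnorm(60), b = rnorm(60))
#' d$label <- as.integer(stats::runif(60) < stats::plogis(2 * d$a - d$b))
#' fit <- cslr_fit(d, features = c("a", "b"),
#'                 config = cslr_config(l2_lambda = 0.01))
#' tidy(fit)
#' @export
cslr_fit <- function(data, features = all_features(), config = cslr_config(),
                     label_col = "label") {
  stopifnot(inherits(config, "cslr_config"))
  if (!label_col %in% names(data)) abort(sprintf("No `%s` column.", label_col))
  y <- as_label01(data[[label_col]])
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present to fit a classifier.")
  }
  x <- feature_matrix(data, features)

  w_outlier <- config$w_outlier
  if (identical(w_outlier, "balanced")) {
    w_outlier <- sum(y == 0) / sum(y == 1)
  }

  if (config$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  opt <- cslr_optimise(xs, y, config$w_normal, w_outlier,
                       config$l2_lambda, config$max_iter, config$tol)

  structure(
    list(
      beta = stats::setNames(opt$beta, features),
      beta0 = opt$beta0,
      feature_names = features,
      scaler = list(center = stats::setNames(center, features),
                    scale = stats::setNames(scale, features)),
      config = config,
      w_outlier_resolved = w_outlier,
      converged = opt$converged,
      final_objective = opt$objective,
      objective_trace = opt$trace,
      iterations = opt$iterations,
      n = length(y),
      n_outliers = sum(y)
    ),
    class = "cslr_fit"
  )
}

#' Predicted outlier probabilities
#'
#' Applies the stored training scaler and the logistic link to new feature
#' rows.
#'
#' @param model A [cslr_fit()] object.
#' @param data Data frame containing the model's feature columns.
#' @return Numeric vector of outlier probabilities in (0, 1).
#' @export
predict_proba <- function(model, data) {
  stopifnot(inherits(model, "cslr_fit"))
  x <- feature_matrix(data, model$feature_names)
  xs <- sweep(sweep(x, 2, model$scaler$center), 2, model$scaler$scale, "/")
  stats::plogis(drop(xs %*% model$beta) + model$beta0)
}

#' Thresholded outlier classification
#'
#' @inheritParams predict_proba
#' @param threshold Decision cutoff; defaults to the fitted config's. A row is
#'   classified 1 (outlier) iff its probability is `>= threshold`.
#' @return Integer vector of 0/1 class labels.
#' @export
classify <- function(model, data, threshold = model$config$threshold) {
  as.integer(predict_proba(model, data) >= threshold)
}

#' @export
predict.cslr_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, newdata) else classify(object, newdata)
}

#' @export
print.cslr_fit <- function(x, ...) {
  cat("<cslr_fit> cost-sensitive logistic regression\n")
  cat(sprintf(
    "  %d features, n = %d (%d outliers); w_outlier/w_normal = %.2f, lambda = %g\n",
    length(x$beta), x$n, x$n_outliers,
    x$w_outlier_resolved / x$config$w_normal, x$config$l2_lambda
  ))
  cat(sprintf(
    "  converged: %s after %d iterations, objective %.6g\n",
    x$converged, x$iterations, x$final_objective
  ))
  invisible(x)
}

#' @rdname cslr_fit
#' @param x A `cslr_fit` object.
#' @param ... Unused.
#' @export
tidy.cslr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(x$beta0, unname(x$beta))
  )
}

#' @rdname cslr_fit
#' @export
glance.cslr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_outliers = x$n_outliers,
    l2_lambda = x$config$l2_lambda,
    weight_ratio = x$w_outlier_resolved / x$config$w_normal,
    converged = x$converged,
    iterations = x$iterations,
    final_objective = x$final_objective
  )
}

#' Serialize / restore a fitted CSLR model as JSON
#'
#' @param model A `cslr_fit`.
#' @param path File path.
#' @return `write_cslr()` returns `path` invisibly; `read_cslr()` returns a
#'   `cslr_fit`.
#' @export
write_cslr <- function(model, path) {
  stopifnot(inherits(model, "cslr_fit"))
  payload <- list(
    feature_names = model$feature_names,
    beta = unname(model$beta),
    beta0 = model$beta0,
    scaler = list(center = unname(model$scaler$center),
                  scale = unname(model$scaler$scale)),
    config = unclass(model$config),
    w_outlier_resolved = model$w_outlier_resolved,
    converged = model$converged,
    final_objective = model$final_objective,
    n = model$n,
    n_outliers = model$n_outliers
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cslr
#' @export
read_cslr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(cslr_config, p$config[setdiff(names(p$config), character(0))])
  structure(
    list(
      beta = stats::setNames(p$beta, p$feature_names),
      beta0 = p$beta0,
      feature_names = p$feature_names,
      scaler = list(center = stats::setNames(p$scaler$center, p$feature_names),
                    scale = stats::setNames(p$scaler$scale, p$feature_names)),
      config = cfg,
      w_outlier_resolved = p$w_outlier_resolved,
      converged = p$converged,
      final_objective = p$final_objective,
      objective_trace = NULL,
      iterations = NA_integer_,
      n = p$n,
      n_outliers = p$n_outliers
    ),
    class = "cslr_fit"
  )
}
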