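# ggplot2 graphics for envelopes, ROC curves and learning curves.

#' Plot a recording's combined envelope with detected twitches
#'
#' @param rec A one-row recordings tibble.
#' @param params A [feature_params()].
#' @return A ggplot object: the combined envelope with the four detected
#'   twitch peaks and their integration windows.
#' @export
plot_recording <- function(rec, params = feature_params()) {
  env <- combine_axes(rec, gyro_weight = params$gyro_weight)
  tw <- detect_twitches(env, params)
  pk <- tw$peaks
  pk$twitch <- paste0("T", seq_len(nrow(pk)))
  ggplot2::ggplot(env, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_rect(
      data = pk, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = env$t[.data$window_start + 1],
        xmax = env$t[pmin(.data$window_end, nrow(env) - 1) + 1],
        ymin = -Inf, ymax = Inf, fill = .data$twitch
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_point(
      data = pk,
      ggplot2::aes(x = .data$peak_time, y = env$v[.data$peak_index + 1],
                   colour = .data$twitch),
      size = 2
    ) +
    ggplot2::labs(
      x = "time (centiseconds)",
      y = "combined acceleration/angulation envelope",
      title = if ("measurement_id" %in% names(rec)) rec$measurement_id else NULL,
      subtitle = if ("label" %in% names(rec)) rec$label else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tof_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (centiseconds)",
                  y = "combined envelope") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tof_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tof_learning_curves <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$size, y = .data$mean_score,
                 colour = .data$partition)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_score - .data$sd_score,
        ymax = .data$mean_score + .data$sd_score,
        fill = .data$partition
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::labs(x = "training instances", y = "score") +
    ggplot2::theme_minimal()
  if ("model_tag" %in% names(object)) {
    p + ggplot2::facet_grid(model_tag ~ metric)
  } else {
    p + ggplot2::facet_wrap(~metric)
  }
}

#' ROC curves for the fitted models of an experiment
#'
#' @param experiment A [run_experiment()] result.
#' @param partition `"test"` (default) or `"train"`.
#' @return A ggplot with one ROC curve per feature set.
#' @export
plot_experiment_roc <- function(experiment, partition = c("test", "train")) {
  partition <- match.arg(partition)
  d <- experiment$split[[partition]]
  curves <- purrr::imap(experiment$fits, function(fit, tag) {
    rc <- roc_curve(as_label01(d$label), predict_proba(fit, d))
    rc$model <- sprintf("%s (AUC %.2f)", tag, attr(rc, "auc"))
    rc
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
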