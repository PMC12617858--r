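#' Plot a cross-validation report
#'
#' Draws PCC and MSE side by side — the harness's dual-metric contract
#' carries into the figures. For a feature-count sweep the x axis is the
#' marker count (log2 scale); for a reference-fraction sweep it is the
#' fraction, with line type distinguishing selection strategies; otherwise
#' per-fold points are shown by model.
#'
#' @param object A `gp_eval` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("pcc", "mse"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("pcc", "mse"),
                        labels = c("Pearson r", "MSE"))
  if ("count" %in% names(long)) {
    agg <- dplyr::summarise(
      dplyr::group_by(long, .data$model, .data$count, .data$metric),
      value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$count, y = .data$value,
                                           colour = .data$model)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_continuous(trans = "log2") +
      ggplot2::labs(x = "number of features", y = NULL)
  } else if ("fraction" %in% names(long)) {
    agg <- dplyr::summarise(
      dplyr::group_by(long, .data$strategy, .data$fraction, .data$metric),
      value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$fraction,
                                           y = .data$value,
                                           colour = .data$strategy)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "reference fraction", y = NULL)
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                            colour = .data$model)) +
      ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1,
                                                              height = 0)) +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::guides(colour = "none")
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot the training-loss trajectory of an obscured network
#'
#' @param object A trained `obscured_net`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.obscured_net <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean mini-batch MSE") +
    ggplot2::theme_minimal()
}

#' Plot a training-versus-test squared-error heatmap
#'
#' @param heatmap Matrix from [mse_heatmap()].
#' @return A ggplot object (tiles: training instances x test instances).
#' @export
plot_mse_heatmap <- function(heatmap) {
  df <- tibble::tibble(
    train = rep(seq_len(nrow(heatmap)), times = ncol(heatmap)),
    test = rep(seq_len(ncol(heatmap)), each = nrow(heatmap)),
    sq_error = as.vector(heatmap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train,
                                   fill = .data$sq_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "squared error") +
    ggplot2::labs(x = "test instance", y = "training instance") +
    ggplot2::theme_minimal()
}

#' Scatter plot of actual versus predicted phenotypes
#'
#' The dual-metric diagnostic view: a moderate correlation can coexist with
#' visibly compressed predictions, which only the MSE (and this plot) reveal.
#'
#' @param report A `gp_eval` with attached predictions.
#' @param models Optional subset of model names to show.
#' @return A ggplot object faceted by model.
#' @export
plot_predictions <- function(report, models = NULL) {
  prd <- cv_predictions(report)
  if (is.null(prd) || nrow(prd) == 0L) stop("report carries no predictions")
  if (!is.null(models)) prd <- dplyr::filter(prd, .data$model %in% models)
  ggplot2::ggplot(prd, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "actual (standardized)", y = "predicted") +
    ggplot2::theme_minimal()
}
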