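#' Plot the training and validation loss curves
#'
#' @param object A `train_history` or `clock_fit`.
#' @param ... Unused.
#' @return A ggplot: per-epoch MSE (years^2) on a log scale, with the best
#'   epoch marked.
#' @method autoplot train_history
#' @export
autoplot.train_history <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  df$set <- sub("_loss$", "", df$set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = expression(MSE ~ (years^2)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot clock_fit
#' @export
autoplot.clock_fit <- function(object, ...) autoplot(object$history, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted versus chronological age scatter plot
#'
#' @param predictions Tibble with `age` and `predicted_age` columns.
#' @return A ggplot with the identity line; points on it are perfectly
#'   predicted samples.
#' @export
plot_predictions <- function(predictions) {
  stopifnot(all(c("age", "predicted_age") %in% names(predictions)))
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$age, y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted age (years)") +
    ggplot2::theme_minimal()
}

#' Channel-gate profile, optionally annotated with ground truth
#'
#' @param gates Tibble from [channel_gate_profile()].
#' @param informative_channels Optional integer vector of channels known to
#'   contain age-informative loci (from a synthetic cohort's truth).
#' @return A ggplot of mean gate per channel.
#' @export
plot_gate_profile <- function(gates, informative_channels = NULL) {
  stopifnot(all(c("channel", "gate") %in% names(gates)))
  if (!is.null(informative_channels)) {
    gates$informative <- gates$channel %in% informative_channels
    p <- ggplot2::ggplot(gates, ggplot2::aes(x = .data$channel,
                                             y = .data$gate,
                                             fill = .data$informative))
  } else {
    p <- ggplot2::ggplot(gates, ggplot2::aes(x = .data$channel,
                                             y = .data$gate))
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "channel", y = "mean excitation gate") +
    ggplot2::theme_minimal()
}

#' Per-group mean signed error bar chart
#'
#' @param summary Tibble from [per_group_error_summary()].
#' @return A ggplot of mean signed error (predicted - actual) per group.
#' @export
plot_group_errors <- function(summary) {
  stopifnot(all(c("group", "mean_error") %in% names(summary)))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group,
                                        y = .data$mean_error)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "mean signed error (years)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
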