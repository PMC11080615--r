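#' Coefficient of determination of an age prediction
#'
#' `R^2 = 1 - SSE / SST`, where `SSE = sum((pred - actual)^2)` and
#' `SST = sum((actual - mean(actual))^2)`. Equals 1 exactly when every
#' prediction matches its target; can be negative for a model worse than the
#' mean predictor.
#'
#' @param predicted,actual Numeric vectors of equal length (years); `actual`
#'   must not be constant.
#' @return A real number `<= 1`.
#' @export
r_squared <- function(predicted, actual) {
  check_pred_pair(predicted, actual)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("SST is zero: actual ages are all identical.",
                     call. = FALSE)
  1 - sum((predicted - actual)^2) / sst
}

#' Mean absolute, mean squared and median absolute prediction error
#'
#' `mae()` is the mean of `|predicted - actual|` in years; `mse()` the mean
#' of its square in years-squared; `med_abs_error()` the median of
#' `|predicted - actual|` (for an even count, the mean of the two central
#' order statistics). The median absolute error is the conventional primary
#' accuracy measure for epigenetic clocks because it is robust to the few
#' samples every clock mispredicts badly.
#'
#' @inheritParams r_squared
#' @return A non-negative real.
#' @export
mae <- function(predicted, actual) {
  check_pred_pair(predicted, actual)
  mean(abs(predicted - actual))
}

#' @rdname mae
#' @export
mse <- function(predicted, actual) {
  check_pred_pair(predicted, actual)
  mean((predicted - actual)^2)
}

#' @rdname mae
#' @export
med_abs_error <- function(predicted, actual) {
  check_pred_pair(predicted, actual)
  stats::median(abs(predicted - actual))
}

check_pred_pair <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` differ in length.", call. = FALSE)
  }
  if (length(predicted) < 1) stop("Need at least one sample.", call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(actual))) {
    stop("Predictions and ages must be finite.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Summary metrics for a table of age predictions
#'
#' @param data Data frame with one row per sample.
#' @param truth,estimate Column names (unquoted or character) holding the
#'   chronological and predicted ages; defaults `age` and `predicted_age`.
#' @return One-row tibble: `n`, `r_squared`, `mae` (years), `mse`
#'   (years^2), `med` (years).
#' @export
#' @examples
#' clock_metrics(data.frame(age = c(30, 40, 50),
#'                          predicted_age = c(31, 38, 55)))
clock_metrics <- function(data, truth = "age", estimate = "predicted_age") {
  truth <- rlang::as_name(rlang::enquo(truth))
  estimate <- rlang::as_name(rlang::enquo(estimate))
  actual <- data[[truth]]
  predicted <- data[[estimate]]
  if (is.null(actual) || is.null(predicted)) {
    stop("Columns `", truth, "` and `", estimate, "` are required.",
         call. = FALSE)
  }
  tibble::tibble(
    n = length(actual),
    r_squared = r_squared(predicted, actual),
    mae = mae(predicted, actual),
    mse = mse(predicted, actual),
    med = med_abs_error(predicted, actual))
}

#' Per-group signed-error summary
#'
#' Summarises prediction error within groups (typically tissue or dataset):
#' the mean signed error `predicted - actual` (positive = over-ageing, the
#' usual per-tissue bias display), plus the group's median and mean absolute
#' error.
#'
#' @param predictions Tibble with `sample_id`, `age`, `predicted_age`
#'   (as returned by [predict.clock_model()] with metadata, or
#'   `fit$test_predictions`). An `age` column in `meta` is used when
#'   `predictions` lacks one.
#' @param meta Sample metadata covering every prediction row.
#' @param group_key Metadata column to group by (character), e.g. `"tissue"`
#'   or `"dataset_id"`.
#' @return Tibble with one row per group: `group`, `n`, `mean_error`, `med`,
#'   `mae` (years).
#' @export
per_group_error_summary <- function(predictions, meta, group_key = "tissue") {
  meta <- as_sample_meta(meta)
  if (!group_key %in% names(meta)) {
    stop("Metadata has no column `", group_key, "`.", call. = FALSE)
  }
  absent <- setdiff(predictions$sample_id, meta$sample_id)
  if (length(absent) > 0) {
    stop("Samples without metadata: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (and %d more)", length(absent) - 5),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(predictions, "sample_id",
                  dplyr::any_of(c("age", "predicted_age"))),
    dplyr::select(meta, "sample_id", grp = dplyr::all_of(group_key),
                  meta_age = "age"),
    by = "sample_id")
  if (!"age" %in% names(joined)) joined$age <- joined$meta_age
  joined |>
    dplyr::mutate(err = .data$predicted_age - .data$age) |>
    dplyr::group_by(group = .data$grp) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_error = mean(.data$err),
                     med = stats::median(abs(.data$err)),
                     mae = mean(abs(.data$err)),
                     .groups = "drop")
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-epoch loss curve of a training run
#'
#' @param x A `train_history` or `clock_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss` (years^2).
#' @method tidy train_history
#' @export
tidy.train_history <- function(x, ...) x$history

#' @method tidy clock_fit
#' @export
tidy.clock_fit <- function(x, ...) tidy(x$history)

#' One-row summary of a training run
#'
#' @param x A `train_history` or `clock_fit`.
#' @param ... Unused.
#' @return One-row tibble: `epochs_run`, `best_epoch`, `best_val_loss` and,
#'   for a `clock_fit` with a test split, the test-set metrics.
#' @method glance train_history
#' @export
glance.train_history <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss)
}

#' @method glance clock_fit
#' @export
glance.clock_fit <- function(x, ...) {
  out <- glance(x$history)
  if (!is.null(x$test_metrics)) {
    out <- dplyr::bind_cols(out, dplyr::rename_with(
      x$test_metrics, ~ paste0("test_", .x)))
  }
  out
}
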