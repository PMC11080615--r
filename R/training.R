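#' Optimization settings for clock training
#'
#' Defaults follow the reference training recipe for the full-panel clock:
#' Adam with learning rate 0.05, batch size 512, at most 150 epochs, mean
#' squared error loss, and early stopping that returns the parameters of the
#' epoch with the lowest validation loss.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size; the last partial batch is kept, but
#'   training batches of size 1 are skipped (batch normalization needs at
#'   least two samples for a batch statistic).
#' @param max_epochs Maximum number of passes over the training set.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed controlling shuffling, initialization (via
#'   [fit_clock()]) and dropout.
#' @param split_fractions Train/validation/test fractions summing to 1. The
#'   default `c(0.81, 0.09, 0.10)` applied to 10,589 samples yields the
#'   canonical 8,577 / 953 / 1,059 partition.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.05, batch_size = 512L,
                         max_epochs = 150L, patience = 20L, seed = 1L,
                         split_fractions = c(0.81, 0.09, 0.10)) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience <= max_epochs,
            length(split_fractions) == 3, all(split_fractions >= 0),
            abs(sum(split_fractions) - 1) <= 1e-9)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 split_fractions = split_fractions),
            class = "train_config")
}

#' Shuffle-and-split sample indices into train/validation/test sets
#'
#' Indices are permuted with `seed`, then the first `floor(n * f_train)` go
#' to training, the next `floor(n * f_val)` to validation and the remainder
#' to test, so the three sets are disjoint and exhaustive.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Length-3 non-negative fractions summing to 1.
#' @param seed Integer seed for the permutation.
#' @return Named list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  stopifnot(n >= 3, length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) <= 1e-9)
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  if (n_train < 1) stop("Split fractions produce an empty training set.",
                        call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[setdiff(seq_len(n), seq_len(n_train + n_val))])
}

# recursive Adam update over the gradient tree; `state` mirrors `grads`
adam_step <- function(params, grads, state, step, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  # align by name where names exist (top-level blocks), by position inside
  # the unnamed per-layer list
  keys <- if (is.null(names(grads))) seq_along(grads) else names(grads)
  slot <- function(lst, key) {
    if (is.character(key)) lst[[key]]
    else if (key <= length(lst)) lst[[key]] else NULL
  }
  for (nm in keys) {
    g <- grads[[nm]]
    if (is.list(g)) {
      st0 <- slot(state, nm)
      res <- adam_step(params[[nm]], g, if (is.null(st0)) list() else st0,
                       step, lr, beta1, beta2, eps)
      params[[nm]] <- res$params
      state[[nm]] <- res$state
    } else {
      st <- slot(state, nm)
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^step)
      vhat <- st$v / (1 - beta2^step)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  }
  list(params = params, state = state)
}

mse_loss <- function(pred, y) mean((pred - y)^2)

#' Train a clock model with Adam and early stopping
#'
#' Minimises mean squared error in years-squared over minibatches. After
#' every epoch the validation loss is computed in evaluation mode; the
#' parameters (including batch-normalization running statistics) of the
#' epoch with the lowest validation loss are snapshotted and restored at the
#' end, so the returned model reproduces `best_val_loss` exactly. Training
#' stops at `max_epochs` or once `patience` epochs pass without a new
#' validation minimum.
#'
#' @param model A `clock_model` from [build_clock()].
#' @param x_train,x_val Numeric matrices (samples x loci) of beta values.
#' @param y_train,y_val Numeric vectors of chronological ages in years.
#' @param cfg A [train_config()].
#' @return A list of class `clock_fit` with elements `model` (best-epoch
#'   parameters) and `history` (a `train_history`).
#' @export
train_clock <- function(model, x_train, y_train, x_val, y_val,
                        cfg = train_config()) {
  stopifnot(inherits(model, "clock_model"), inherits(cfg, "train_config"),
            nrow(x_train) == length(y_train), nrow(x_val) == length(y_val),
            nrow(x_train) >= 1, nrow(x_val) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  n <- nrow(x_train)
  state <- list()
  step <- 0L
  best_val <- Inf
  best_epoch <- NA_integer_
  best_params <- NULL
  since_best <- 0L
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  warned_singleton <- FALSE

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_sse <- 0
    ep_n <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      if (length(idx) == 1L) {
        if (!warned_singleton) {
          warning("Skipping a training batch of size 1 (batch normalization ",
                  "needs >= 2 samples).", call. = FALSE)
          warned_singleton <- TRUE
        }
        next
      }
      xb <- x_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      fw <- clock_forward(model, xb, training = TRUE)
      model <- fw$model   # running statistics advanced
      loss <- mse_loss(fw$pred, yb)
      if (!is.finite(loss)) {
        stop(sprintf("Non-finite training loss at epoch %d; try a lower learning rate.",
                     epoch), call. = FALSE)
      }
      dpred <- 2 * (fw$pred - yb) / length(yb)
      grads <- clock_backward(model, fw$cache, dpred)
      step <- step + 1L
      upd <- adam_step(model$params, grads, state, step, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_sse <- ep_sse + loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val_pred <- clock_forward(model, x_val, training = FALSE)$pred
    val_loss <- mse_loss(val_pred, y_val)
    if (!is.finite(val_loss)) {
      stop(sprintf("Non-finite validation loss at epoch %d.", epoch),
           call. = FALSE)
    }
    hist_train <- c(hist_train, ep_sse / max(ep_n, 1L))
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_epoch <- epoch
      best_params <- model$params
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  model$params <- best_params
  history <- structure(list(
    history = tibble::tibble(epoch = seq_along(hist_train),
                             train_loss = hist_train,
                             val_loss = hist_val),
    best_epoch = best_epoch,
    best_val_loss = best_val
  ), class = "train_history")
  structure(list(model = model, history = history, train_cfg = cfg),
            class = "clock_fit")
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history: %d epochs, best epoch %d, best val MSE %.3f yr^2>\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
print.clock_fit <- function(x, ...) {
  print(x$model)
  print(x$history)
  invisible(x)
}

#' Fit a methylation clock to a cohort
#'
#' High-level wrapper: shuffles and splits the samples, builds the network,
#' trains with early stopping and evaluates on the held-out test split.
#'
#' @param bm A fully imputed [beta_matrix()] whose column order defines the
#'   model's locus panel.
#' @param meta Sample metadata (see [as_sample_meta()]) covering every sample
#'   in `bm`.
#' @param clock_cfg A [clock_config()] whose input length equals `ncol(bm)`.
#' @param cfg A [train_config()]; its `seed` drives the split,
#'   initialization and dropout.
#' @param variant `"perseclock"` or `"plain_mlp"`.
#' @return A `clock_fit` with additional elements `split` (index sets),
#'   `test_predictions` (tibble: `sample_id`, `age`, `predicted_age`) and
#'   `test_metrics` (one-row tibble from [clock_metrics()]).
#' @export
fit_clock <- function(bm, meta, clock_cfg, cfg = train_config(),
                      variant = c("perseclock", "plain_mlp")) {
  variant <- match.arg(variant)
  stopifnot(is_beta_matrix(bm), inherits(clock_cfg, "clock_config"))
  if (anyNA(bm)) {
    stop("Beta matrix contains missing values; run impute_missing() first.",
         call. = FALSE)
  }
  if (ncol(bm) != input_length(clock_cfg)) {
    stop(sprintf("Matrix has %d loci but clock_config implies %d.",
                 ncol(bm), input_length(clock_cfg)), call. = FALSE)
  }
  meta <- as_sample_meta(meta)
  missing_meta <- setdiff(rownames(bm), meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("Samples without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  ages <- meta$age[match(rownames(bm), meta$sample_id)]
  split <- split_dataset(nrow(bm), cfg$split_fractions, cfg$seed)
  X <- unclass(bm)
  model <- build_clock(clock_cfg, variant, seed = cfg$seed)
  model$panel <- colnames(bm)
  fit <- train_clock(model,
                     X[split$train, , drop = FALSE], ages[split$train],
                     X[split$val, , drop = FALSE], ages[split$val],
                     cfg)
  fit$split <- split
  test_pred <- stats::predict(fit$model,
                              X[split$test, , drop = FALSE])
  fit$test_predictions <- tibble::tibble(
    sample_id = rownames(bm)[split$test],
    age = ages[split$test],
    predicted_age = test_pred$predicted_age)
  fit$test_metrics <- clock_metrics(fit$test_predictions)
  fit
}

#' Predict ages for a beta matrix
#'
#' Evaluation-mode batch prediction: dropout off, batch normalization on
#' running statistics, so predictions are deterministic and independent of
#' the batch size used at inference (single samples included).
#'
#' @param object A `clock_model`.
#' @param newdata A fully imputed [beta_matrix()] (locus order must match the
#'   model's panel when one is attached) or a plain numeric matrix.
#' @param meta Optional sample metadata; when given, the chronological `age`
#'   column is joined onto the result.
#' @param ... Unused.
#' @return Tibble with `sample_id` and `predicted_age` (years), plus `age`
#'   when `meta` is supplied.
#' @export
predict.clock_model <- function(object, newdata, meta = NULL, ...) {
  X <- as_input_matrix(newdata, object)
  pred <- clock_forward(object, X, training = FALSE)$pred
  out <- tibble::tibble(
    sample_id = if (is.null(rownames(X))) as.character(seq_len(nrow(X)))
                else rownames(X),
    predicted_age = as.numeric(pred))
  if (!is.null(meta)) {
    meta <- as_sample_meta(meta)
    out <- dplyr::left_join(out,
                            dplyr::select(meta, "sample_id", "age"),
                            by = "sample_id")
  }
  out
}

#' @export
predict.clock_fit <- function(object, newdata, meta = NULL, ...) {
  stats::predict(object$model, newdata, meta = meta, ...)
}
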