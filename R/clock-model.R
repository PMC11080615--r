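#' Architecture configuration for a methylation clock network
#'
#' The network views the length-`L` beta vector of one sample as a
#' three-dimensional block of shape `block_rows x block_cols x channels`
#' (`L = block_rows * block_cols * channels`), with consecutive loci placed
#' in consecutive channels. The channel-attention block summarises each
#' channel by its mean (squeeze), passes the summary through a two-layer
#' bottleneck (excitation) and rescales each channel by the resulting
#' sigmoid gate before a multilayer-perceptron regression head predicts age.
#'
#' @param block_rows,block_cols,channels Block geometry. The full-panel
#'   default `3 x 6 x 1362` covers the 24,516 CpG loci common to the
#'   Illumina 27K/450K/850K platforms; tests and simulations typically use a
#'   smaller geometry such as `clock_config(channels = 24)` (432 loci).
#' @param se_reduction Bottleneck divisor of the excitation block; hidden
#'   width is `max(1, channels %/% se_reduction)`. Defaults to 16, capped at
#'   the channel count for small geometries.
#' @param hidden_width,hidden_depth Width and number of hidden layers of the
#'   regression head (each hidden layer: linear, LeakyReLU, batch
#'   normalization, dropout).
#' @param dropout_rate Dropout probability in `[0, 1)` applied after each
#'   hidden layer during training.
#' @param leaky_slope Negative-side slope of the LeakyReLU activation.
#'
#' @return A `clock_config` list; `input_length(cfg)` gives the implied
#'   input dimension.
#' @export
clock_config <- function(block_rows = 3L, block_cols = 6L, channels = 1362L,
                         se_reduction = min(16L, channels), hidden_width = 32L,
                         hidden_depth = 4L, dropout_rate = 0.1,
                         leaky_slope = 0.01) {
  stopifnot(block_rows >= 1, block_cols >= 1, channels >= 1,
            se_reduction >= 1, se_reduction <= channels,
            hidden_width >= 1, hidden_depth >= 1,
            dropout_rate >= 0, dropout_rate < 1, leaky_slope > 0)
  structure(list(
    block_rows = as.integer(block_rows),
    block_cols = as.integer(block_cols),
    channels = as.integer(channels),
    se_reduction = as.integer(se_reduction),
    hidden_width = as.integer(hidden_width),
    hidden_depth = as.integer(hidden_depth),
    dropout_rate = dropout_rate,
    leaky_slope = leaky_slope
  ), class = "clock_config")
}

#' @rdname clock_config
#' @param cfg A `clock_config`.
#' @export
input_length <- function(cfg) {
  cfg$block_rows * cfg$block_cols * cfg$channels
}

#' @export
print.clock_config <- function(x, ...) {
  cat(sprintf(
    "<clock_config: %d x %d x %d blocks (input %d), SE reduction %d, head %d x %d>\n",
    x$block_rows, x$block_cols, x$channels, input_length(x),
    x$se_reduction, x$hidden_depth, x$hidden_width))
  invisible(x)
}

# channel index of each input position: consecutive loci -> consecutive
# channels (locus i lands in channel ((i - 1) mod channels) + 1)
channel_of <- function(cfg) {
  ((seq_len(input_length(cfg)) - 1L) %% cfg$channels) + 1L
}

#' Reshape a beta vector into the channel-block tensor
#'
#' Element `i` of `x` is placed in channel `((i - 1) mod channels) + 1`, at
#' within-channel position `(i - 1) %/% channels` in row-major order, so
#' adjacent loci land in different (consecutive) channels.
#'
#' @param x Numeric vector of length `input_length(cfg)`.
#' @param cfg A [clock_config()].
#' @return A 3-D array of dimension
#'   `c(block_rows, block_cols, channels)`.
#' @export
reshape_to_blocks <- function(x, cfg) {
  L <- input_length(cfg)
  if (length(x) != L) {
    stop(sprintf("Input length %d does not equal block_rows*block_cols*channels = %d.",
                 length(x), L), call. = FALSE)
  }
  aperm(array(as.numeric(x), dim = c(cfg$channels, cfg$block_cols, cfg$block_rows)),
        c(3L, 2L, 1L))
}

#' @rdname reshape_to_blocks
#' @param blocks A block tensor produced by `reshape_to_blocks()`.
#' @return `flatten_blocks()` returns the original length-`L` vector.
#' @export
flatten_blocks <- function(blocks, cfg) {
  stopifnot(identical(dim(blocks),
                      c(cfg$block_rows, cfg$block_cols, cfg$channels)))
  as.numeric(aperm(blocks, c(3L, 2L, 1L)))
}

#' Per-channel mean of a block tensor (squeeze step)
#'
#' @param blocks A block tensor (`block_rows x block_cols x channels`).
#' @return Numeric vector of length `channels`; entry `c` is the arithmetic
#'   mean of the `block_rows * block_cols` values in channel `c`.
#' @export
global_average_pool <- function(blocks) {
  stopifnot(length(dim(blocks)) == 3)
  apply(blocks, 3, mean)
}

#' Channel gates from the excitation block
#'
#' Computes `sigmoid(W2 %*% relu(W1 %*% pooled + b1) + b2)`: a two-layer
#' bottleneck over the pooled channel summaries, yielding one gate per
#' channel strictly inside `(0, 1)`.
#'
#' @param pooled Numeric vector of per-channel means
#'   (see [global_average_pool()]).
#' @param model A `clock_model` of variant `"perseclock"`.
#' @return Numeric vector of gates, class `channel_gates`.
#' @export
excitation <- function(pooled, model) {
  stopifnot(inherits(model, "clock_model"))
  if (model$variant != "perseclock") {
    stop("Excitation requires a perseclock-variant model.", call. = FALSE)
  }
  se <- model$params$se
  if (length(pooled) != nrow(se$W1)) {
    stop(sprintf("Pooled vector length %d != channel count %d.",
                 length(pooled), nrow(se$W1)), call. = FALSE)
  }
  g <- drop(se_gates(matrix(pooled, nrow = 1), se))
  structure(g, class = "channel_gates")
}

se_gates <- function(S, se) {
  z1 <- sweep(S %*% se$W1, 2, se$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% se$W2, 2, se$b2, `+`)
  stats::plogis(z2)
}

#' Rescale each channel of a block tensor by its gate
#'
#' @param blocks A block tensor.
#' @param gates Numeric vector (one gate per channel).
#' @return The tensor with every value in channel `c` multiplied by
#'   `gates[c]`.
#' @export
scale_blocks <- function(blocks, gates) {
  d <- dim(blocks)
  stopifnot(length(d) == 3)
  if (length(gates) != d[3]) {
    stop(sprintf("Gate length %d != channel count %d.", length(gates), d[3]),
         call. = FALSE)
  }
  blocks * rep(as.numeric(gates), each = d[1] * d[2])
}

# ---- model construction ----------------------------------------------------

lin_init <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                  fan_in, fan_out),
       b = stats::runif(fan_out, -bound, bound))
}

#' Build a methylation clock network
#'
#' Initialises a channel-attention perceptron (`variant = "perseclock"`) or a
#' plain multilayer perceptron with the same regression head and no attention
#' block (`variant = "plain_mlp"`, the ablation baseline). Hidden layers are
#' linear, LeakyReLU, batch normalization over `hidden_width` features, then
#' dropout; a single linear unit outputs the predicted age in years. Linear
#' weights and biases are drawn uniformly from
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, reproducibly from `seed`.
#'
#' @param cfg A [clock_config()].
#' @param variant `"perseclock"` or `"plain_mlp"`.
#' @param seed Integer seed for parameter initialization.
#' @return A `clock_model` object.
#' @export
build_clock <- function(cfg, variant = c("perseclock", "plain_mlp"),
                        seed = 1L) {
  stopifnot(inherits(cfg, "clock_config"))
  variant <- match.arg(variant)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- input_length(cfg)
  K <- cfg$channels
  params <- list()
  if (variant == "perseclock") {
    H <- max(1L, K %/% cfg$se_reduction)
    l1 <- lin_init(K, H)
    l2 <- lin_init(H, K)
    params$se <- list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
  }
  widths <- c(L, rep(cfg$hidden_width, cfg$hidden_depth))
  params$head <- lapply(seq_len(cfg$hidden_depth), function(l) {
    lin <- lin_init(widths[l], widths[l + 1])
    c(lin, list(gamma = rep(1, widths[l + 1]),
                beta = rep(0, widths[l + 1]),
                running_mean = rep(0, widths[l + 1]),
                running_var = rep(1, widths[l + 1])))
  })
  params$out <- lin_init(cfg$hidden_width, 1L)
  structure(list(config = cfg, variant = variant, params = params,
                 panel = NULL, seed = as.integer(seed)),
            class = "clock_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model [%s]: input %d, head %d x %d%s>\n",
              x$variant, input_length(x$config),
              x$config$hidden_depth, x$config$hidden_width,
              if (is.null(x$panel)) "" else
                sprintf(", panel of %d loci", length(x$panel))))
  invisible(x)
}

# ---- batched forward pass --------------------------------------------------

# X: n x L matrix. Returns list(pred, cache) where cache holds every
# intermediate needed for backpropagation (training = TRUE) or gate
# inspection (collect_gates = TRUE). Batch normalization uses batch
# statistics in training mode and running statistics in evaluation mode;
# dropout only fires in training mode and draws from the current RNG stream.
clock_forward <- function(model, X, training = FALSE, collect_gates = FALSE,
                          update_running = training) {
  cfg <- model$config
  p <- model$params
  K <- cfg$channels
  RC <- cfg$block_rows * cfg$block_cols
  n <- nrow(X)
  cache <- list(X = X)

  if (model$variant == "perseclock") {
    S <- matrix(0, n, K)
    for (q in seq_len(RC)) S <- S + X[, (q - 1L) * K + seq_len(K), drop = FALSE]
    S <- S / RC
    z1 <- sweep(S %*% p$se$W1, 2, p$se$b1, `+`)
    a1 <- pmax(z1, 0)
    z2 <- sweep(a1 %*% p$se$W2, 2, p$se$b2, `+`)
    G <- stats::plogis(z2)
    H <- X
    for (q in seq_len(RC)) {
      idx <- (q - 1L) * K + seq_len(K)
      H[, idx] <- X[, idx, drop = FALSE] * G
    }
    cache$S <- S; cache$z1 <- z1; cache$a1 <- a1; cache$G <- G
  } else {
    H <- X
    if (collect_gates) cache$G <- NULL
  }

  eps <- 1e-5
  cache$layers <- vector("list", cfg$hidden_depth)
  for (l in seq_len(cfg$hidden_depth)) {
    ly <- p$head[[l]]
    z <- sweep(H %*% ly$W, 2, ly$b, `+`)
    a <- ifelse(z > 0, z, cfg$leaky_slope * z)
    if (training) {
      mu <- colMeans(a)
      v <- colMeans(a^2) - mu^2      # biased batch variance
      if (update_running && n > 1) {
        mom <- 0.1
        model$params$head[[l]]$running_mean <- (1 - mom) * ly$running_mean + mom * mu
        model$params$head[[l]]$running_var <-
          (1 - mom) * ly$running_var + mom * v * n / (n - 1)
      }
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
    }
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(a, 2, mu, `-`), 2, inv_sd, `*`)
    y <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    if (training && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(stats::rbinom(length(y), 1, keep) / keep,
                     nrow(y), ncol(y))
      h_out <- y * mask
    } else {
      mask <- NULL
      h_out <- y
    }
    cache$layers[[l]] <- list(h_in = H, z = z, a = a, mu = mu, v = v,
                              inv_sd = inv_sd, xhat = xhat, mask = mask,
                              batch_stats = training)
    H <- h_out
  }
  pred <- drop(sweep(H %*% p$out$W, 2, p$out$b, `+`))
  cache$h_last <- H
  list(pred = pred, cache = cache, model = model)
}

# gradient of the loss w.r.t. every parameter, given d(loss)/d(pred)
clock_backward <- function(model, cache, dpred) {
  cfg <- model$config
  p <- model$params
  K <- cfg$channels
  RC <- cfg$block_rows * cfg$block_cols
  n <- nrow(cache$X)
  g <- list()

  dP <- matrix(dpred, ncol = 1)
  g$out <- list(W = crossprod(cache$h_last, dP), b = sum(dP))
  dH <- dP %*% t(p$out$W)

  for (l in rev(seq_len(cfg$hidden_depth))) {
    ly <- p$head[[l]]
    cc <- cache$layers[[l]]
    dy <- if (is.null(cc$mask)) dH else dH * cc$mask
    dgamma <- colSums(dy * cc$xhat)
    dbeta <- colSums(dy)
    dxhat <- sweep(dy, 2, ly$gamma, `*`)
    if (isTRUE(cc$batch_stats)) {
      # backprop through batch statistics
      a_c <- sweep(cc$a, 2, cc$mu, `-`)
      dv <- colSums(dxhat * a_c) * (-0.5) * cc$inv_sd^3
      dmu <- -colSums(dxhat) * cc$inv_sd + dv * (-2) * colMeans(a_c)
      da <- sweep(dxhat, 2, cc$inv_sd, `*`) +
        sweep(a_c, 2, dv * 2 / n, `*`) +
        matrix(dmu / n, n, length(dmu), byrow = TRUE)
    } else {
      da <- sweep(dxhat, 2, cc$inv_sd, `*`)
    }
    dz <- da * ifelse(cc$z > 0, 1, cfg$leaky_slope)
    g$head[[l]] <- list(W = crossprod(cc$h_in, dz), b = colSums(dz),
                        gamma = dgamma, beta = dbeta)
    dH <- dz %*% t(ly$W)
  }

  if (model$variant == "perseclock") {
    X <- cache$X
    G <- cache$G
    dG <- matrix(0, n, K)
    for (q in seq_len(RC)) {
      idx <- (q - 1L) * K + seq_len(K)
      dG <- dG + dH[, idx, drop = FALSE] * X[, idx, drop = FALSE]
    }
    dz2 <- dG * G * (1 - G)
    g$se <- list(W2 = crossprod(cache$a1, dz2), b2 = colSums(dz2))
    da1 <- dz2 %*% t(p$se$W2)
    dz1 <- da1 * (cache$z1 > 0)
    g$se$W1 <- crossprod(cache$S, dz1)
    g$se$b1 <- colSums(dz1)
  }
  g
}

#' Predict age for a single beta vector
#'
#' Runs the full forward pass in evaluation mode (dropout off, batch
#' normalization on running statistics): for the `perseclock` variant,
#' `head(flatten(scale(reshape(x), excitation(pool(reshape(x))))))`; for
#' `plain_mlp`, `head(x)`.
#'
#' @param x Numeric beta vector of length `input_length(model$config)`.
#' @param model A `clock_model`.
#' @return A single finite predicted age in years.
#' @export
forward <- function(x, model) {
  stopifnot(inherits(model, "clock_model"))
  if (any(!is.finite(x))) stop("Input contains non-finite values.", call. = FALSE)
  if (length(x) != input_length(model$config)) {
    stop(sprintf("Input length %d != model input length %d.",
                 length(x), input_length(model$config)), call. = FALSE)
  }
  clock_forward(model, matrix(x, nrow = 1), training = FALSE)$pred
}

#' Channel gates of a trained model on a batch of samples
#'
#' @param model A `clock_model` of variant `"perseclock"`.
#' @param X Numeric matrix (samples x loci) or [beta_matrix()].
#' @return Tibble with one row per channel: `channel`, `gate` (mean gate over
#'   the batch).
#' @export
channel_gate_profile <- function(model, X) {
  stopifnot(inherits(model, "clock_model"), model$variant == "perseclock")
  X <- as_input_matrix(X, model)
  fw <- clock_forward(model, X, training = FALSE, collect_gates = TRUE)
  tibble::tibble(channel = seq_len(model$config$channels),
                 gate = colMeans(fw$cache$G))
}

as_input_matrix <- function(X, model) {
  if (is_beta_matrix(X)) {
    if (anyNA(X)) {
      stop("Beta matrix contains missing values; run impute_missing() first.",
           call. = FALSE)
    }
    if (!is.null(model$panel)) {
      if (!identical(colnames(X), model$panel)) {
        stop("Locus order of the beta matrix does not match the model's panel; ",
             "use intersect_loci() with the training panel.", call. = FALSE)
      }
    }
    X <- unclass(X)
  }
  if (any(!is.finite(X))) stop("Input contains non-finite values.", call. = FALSE)
  if (ncol(X) != input_length(model$config)) {
    stop(sprintf("Input has %d loci but the model expects %d.",
                 ncol(X), input_length(model$config)), call. = FALSE)
  }
  X
}

# ---- checkpoints -----------------------------------------------------------

#' Save or load a clock-model checkpoint
#'
#' A checkpoint is a single JSON file holding the architecture configuration,
#' variant, locus panel (if any) and every parameter array at full numeric
#' precision.
#'
#' @param model A `clock_model`.
#' @param path Checkpoint file path (`.json`).
#' @return `write_clock_checkpoint()` returns `path` invisibly;
#'   `read_clock_checkpoint()` returns the restored `clock_model`.
#' @export
write_clock_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  payload <- list(
    format = "perseclock-checkpoint-v1",
    config = unclass(model$config),
    variant = model$variant,
    seed = model$seed,
    panel = model$panel,
    params = model$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_clock_checkpoint
#' @param config Optional [clock_config()]; loading fails if the checkpoint's
#'   stored configuration differs.
#' @export
read_clock_checkpoint <- function(path, config = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "perseclock-checkpoint-v1")) {
    stop("Not a clock checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(clock_config, payload$config)
  if (!is.null(config)) {
    stopifnot(inherits(config, "clock_config"))
    if (!identical(unclass(cfg), unclass(config))) {
      stop("Checkpoint configuration conflicts with the requested clock_config.",
           call. = FALSE)
    }
  }
  params <- payload$params
  # jsonlite restores 2-D arrays as matrices and 1-D as vectors already
  model <- structure(list(config = cfg, variant = payload$variant,
                          params = params,
                          panel = payload$panel,
                          seed = payload$seed),
                     class = "clock_model")
  model
}
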