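test_that("reshape places consecutive loci in consecutive channels", {
  cfg <- clock_config(block_rows = 3, block_cols = 6, channels = 5)
  x <- seq_len(input_length(cfg))
  blocks <- reshape_to_blocks(x, cfg)
  expect_equal(dim(blocks), c(3L, 6L, 5L))
  # element i -> channel ((i-1) mod K)+1 at within-channel position
  # (i-1) %/% K laid out row-major
  for (i in c(1, 2, 5, 6, 37, 90)) {
    ch <- ((i - 1) %% 5) + 1
    p <- (i - 1) %/% 5
    r <- p %/% 6 + 1
    cl <- p %% 6 + 1
    expect_equal(blocks[r, cl, ch], i)
  }
  # round trip
  set.seed(1)
  xr <- runif(90)
  expect_equal(flatten_blocks(reshape_to_blocks(xr, cfg), cfg), xr)
})

test_that("reshape reports both numbers on a length mismatch", {
  cfg <- clock_config(channels = 5)
  expect_error(reshape_to_blocks(1:10, cfg), "10")
  expect_error(reshape_to_blocks(1:10, cfg), "90")
})

test_that("full-panel geometry: 24,516 values in 3 x 6 x 1,362 blocks of 18", {
  cfg <- clock_config()
  expect_equal(input_length(cfg), 24516L)
  x <- runif(24516)
  blocks <- reshape_to_blocks(x, cfg)
  expect_equal(dim(blocks), c(3L, 6L, 1362L))
  expect_equal(length(blocks), 24516L)
  pooled <- global_average_pool(blocks)
  expect_length(pooled, 1362L)
  expect_equal(prod(dim(blocks)[1:2]), 18L)
})

test_that("global average pooling equals the brute-force per-channel mean", {
  cfg <- clock_config(channels = 4)
  x <- runif(input_length(cfg))
  blocks <- reshape_to_blocks(x, cfg)
  pooled <- global_average_pool(blocks)
  # brute force from the flat vector via the index rule
  for (ch in 1:4) {
    expect_equal(pooled[ch], mean(x[seq(ch, 72, by = 4)]))
  }
  const <- array(0.5, dim = c(3, 6, 2))
  expect_equal(global_average_pool(const), c(0.5, 0.5))
})

test_that("excitation is a sigmoid two-layer bottleneck with gates in (0,1)", {
  cfg <- clock_config(block_rows = 1, block_cols = 2, channels = 2,
                      se_reduction = 1)
  model <- build_clock(cfg, "perseclock", seed = 1)
  # zero weights -> sigmoid(0) = 0.5 everywhere
  model0 <- model
  model0$params$se <- lapply(model0$params$se, function(p) p * 0)
  expect_equal(as.numeric(excitation(c(0.3, 0.9), model0)), c(0.5, 0.5))

  # hand-set toy: W1 = [[1,0],[0,1]], b1 = (0.1, -0.2), W2 = [[2,-1],[0,3]],
  # b2 = (0, 0.5); forward pass evaluated by scalar arithmetic
  model$params$se$W1 <- diag(2)
  model$params$se$b1 <- c(0.1, -0.2)
  model$params$se$W2 <- matrix(c(2, 0, -1, 3), 2, 2)
  model$params$se$b2 <- c(0, 0.5)
  s <- c(0.4, 0.7)
  h1 <- max(0.4 + 0.1, 0); h2 <- max(0.7 - 0.2, 0)
  expected <- 1 / (1 + exp(-c(2 * h1 + 0 * h2, -1 * h1 + 3 * h2 + 0.5)))
  expect_equal(as.numeric(excitation(s, model)), expected, tolerance = 1e-12)

  set.seed(2)
  g <- excitation(runif(2, -5, 5), model)
  expect_true(all(g > 0 & g < 1))
  expect_error(excitation(runif(3), model), "length")
})

test_that("scaling multiplies every channel by its gate", {
  blocks <- array(runif(36), dim = c(3, 6, 2))
  expect_equal(scale_blocks(blocks, c(1, 1)), blocks)
  zeroed <- scale_blocks(blocks, c(0, 1))
  expect_true(all(zeroed[, , 1] == 0))
  expect_equal(zeroed[, , 2], blocks[, , 2])
  g <- runif(2)
  scaled <- scale_blocks(blocks, g)
  for (ch in 1:2) expect_equal(scaled[, , ch], blocks[, , ch] * g[ch])
  expect_error(scale_blocks(blocks, c(0.5, 0.5, 0.5)), "Gate length")
})

test_that("head geometry, seeded init and variant parameter sets are correct", {
  cfg <- clock_config(channels = 24)
  m <- build_clock(cfg, "perseclock", seed = 7)
  widths <- vapply(m$params$head, function(l) ncol(l$W), integer(1))
  expect_equal(widths, rep(32L, 4L))
  expect_equal(dim(m$params$out$W), c(32L, 1L))
  expect_equal(nrow(m$params$head[[1]]$W), input_length(cfg))

  m2 <- build_clock(cfg, "perseclock", seed = 7)
  expect_identical(m$params, m2$params)
  m3 <- build_clock(cfg, "perseclock", seed = 8)
  expect_false(identical(m$params$head[[1]]$W, m3$params$head[[1]]$W))

  plain <- build_clock(cfg, "plain_mlp", seed = 7)
  expect_null(plain$params$se)
})

test_that("forward reduces to the plain head on 0.5x when excitation is zeroed", {
  cfg <- clock_config(channels = 6, dropout_rate = 0)
  perse <- build_clock(cfg, "perseclock", seed = 3)
  perse$params$se <- lapply(perse$params$se, function(p) p * 0)
  plain <- build_clock(cfg, "plain_mlp", seed = 3)
  plain$params$head <- perse$params$head
  plain$params$out <- perse$params$out
  set.seed(4)
  x <- runif(input_length(cfg))
  expect_equal(forward(x, perse), forward(0.5 * x, plain), tolerance = 1e-12)
})

test_that("gates forced to one make the attention clock equal the plain MLP", {
  cfg <- clock_config(channels = 6)
  perse <- build_clock(cfg, "perseclock", seed = 5)
  perse$params$se$W1 <- perse$params$se$W1 * 0
  perse$params$se$W2 <- perse$params$se$W2 * 0
  perse$params$se$b1 <- perse$params$se$b1 * 0
  perse$params$se$b2 <- rep(500, cfg$channels)  # sigmoid(500) == 1 in doubles
  plain <- build_clock(cfg, "plain_mlp", seed = 5)
  plain$params$head <- perse$params$head
  plain$params$out <- perse$params$out
  set.seed(6)
  x <- runif(input_length(cfg))
  expect_identical(forward(x, perse), forward(x, plain))
})

test_that("a hand-evaluated tiny network matches forward()", {
  # single channel, head of one hidden unit pair: composition computed with
  # explicit matrix algebra, evaluation-mode batch norm (running stats 0/1)
  cfg <- clock_config(block_rows = 3, block_cols = 6, channels = 1,
                      se_reduction = 1, hidden_width = 2, hidden_depth = 1,
                      dropout_rate = 0, leaky_slope = 0.01)
  m <- build_clock(cfg, "perseclock", seed = 9)
  x <- seq(0.05, 0.90, length.out = 18)
  s <- mean(x)
  h1 <- pmax(s * m$params$se$W1 + m$params$se$b1, 0)
  gate <- plogis(drop(h1 %*% m$params$se$W2) + m$params$se$b2)
  xs <- x * gate
  ly <- m$params$head[[1]]
  z <- drop(xs %*% ly$W) + ly$b
  a <- ifelse(z > 0, z, 0.01 * z)
  xhat <- (a - ly$running_mean) / sqrt(ly$running_var + 1e-5)
  y <- ly$gamma * xhat + ly$beta
  expected <- drop(y %*% m$params$out$W) + m$params$out$b
  expect_equal(forward(x, m), expected, tolerance = 1e-12)
})

test_that("forward is deterministic in evaluation mode and rejects bad input", {
  cfg <- clock_config(channels = 6)
  m <- build_clock(cfg, "perseclock", seed = 11)
  x <- runif(input_length(cfg))
  expect_identical(forward(x, m), forward(x, m))
  expect_error(forward(c(x[-1], NaN), m), "finite")
  expect_error(forward(x[-1], m), "length")
})

test_that("gates are invariant to permutations within a channel", {
  cfg <- clock_config(channels = 6)
  m <- build_clock(cfg, "perseclock", seed = 12)
  set.seed(13)
  x <- runif(input_length(cfg))
  blocks <- reshape_to_blocks(x, cfg)
  g1 <- excitation(global_average_pool(blocks), m)
  # shuffle positions inside channel 3 only
  perm <- sample(18)
  shuffled <- blocks
  shuffled[, , 3] <- array(as.numeric(blocks[, , 3])[perm], dim = c(3, 6))
  g2 <- excitation(global_average_pool(shuffled), m)
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- clock_config(block_rows = 2, block_cols = 3, channels = 4,
                      se_reduction = 2, hidden_width = 3, hidden_depth = 2,
                      dropout_rate = 0)
  m <- build_clock(cfg, "perseclock", seed = 42)
  set.seed(7)
  X <- matrix(runif(5 * input_length(cfg)), 5)
  y <- runif(5, 20, 80)
  loss_at <- function(model) {
    fw <- perseclock:::clock_forward(model, X, training = TRUE,
                                     update_running = FALSE)
    mean((fw$pred - y)^2)
  }
  fw <- perseclock:::clock_forward(m, X, training = TRUE,
                                   update_running = FALSE)
  g <- perseclock:::clock_backward(m, fw$cache, 2 * (fw$pred - y) / 5)
  h <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    mp <- m; mp$params$se[[nm]][1] <- mp$params$se[[nm]][1] + h
    mm <- m; mm$params$se[[nm]][1] <- mm$params$se[[nm]][1] - h
    expect_equal(g$se[[nm]][1], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-4)
  }
  for (l in 1:2) for (nm in c("W", "gamma", "beta")) {
    mp <- m; mp$params$head[[l]][[nm]][1] <- mp$params$head[[l]][[nm]][1] + h
    mm <- m; mm$params$head[[l]][[nm]][1] <- mm$params$head[[l]][[nm]][1] - h
    expect_equal(g$head[[l]][[nm]][1], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-4)
  }
  mp <- m; mp$params$out$W[1] <- mp$params$out$W[1] + h
  mm <- m; mm$params$out$W[1] <- mm$params$out$W[1] - h
  expect_equal(g$out$W[1], (loss_at(mp) - loss_at(mm)) / (2 * h),
               tolerance = 1e-4)
})

test_that("every parameter block receives gradient signal on some batch", {
  cfg <- clock_config(block_rows = 2, block_cols = 3, channels = 4,
                      se_reduction = 2, hidden_width = 3, hidden_depth = 2,
                      dropout_rate = 0)
  m <- build_clock(cfg, "perseclock", seed = 21)
  set.seed(22)
  seen <- NULL
  for (rep in 1:3) {
    X <- matrix(runif(8 * input_length(cfg)), 8)
    y <- runif(8, 10, 90)
    fw <- perseclock:::clock_forward(m, X, training = TRUE,
                                     update_running = FALSE)
    g <- perseclock:::clock_backward(m, fw$cache, 2 * (fw$pred - y) / 8)
    flat <- abs(unlist(g))
    seen <- if (is.null(seen)) flat > 0 else seen | (flat > 0)
  }
  expect_true(all(seen))
})

test_that("forward is numerically continuous in its input", {
  cfg <- clock_config(channels = 6)
  m <- build_clock(cfg, "perseclock", seed = 31)
  set.seed(32)
  x <- runif(input_length(cfg))
  f0 <- forward(x, m)
  for (i in sample(length(x), 5)) {
    d_coarse <- abs(forward(replace(x, i, x[i] + 1e-3), m) - f0) / 1e-3
    d_fine <- abs(forward(replace(x, i, x[i] + 1e-6), m) - f0) / 1e-6
    # difference quotients agree in scale: O(eps) perturbation response
    expect_lt(d_fine, 10 * max(d_coarse, 1))
  }
})

test_that("checkpoints round-trip and refuse a conflicting configuration", {
  cfg <- clock_config(channels = 6)
  m <- build_clock(cfg, "perseclock", seed = 14)
  m$panel <- sprintf("cg%05d", seq_len(input_length(cfg)))
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_checkpoint(m, path)
  back <- read_clock_checkpoint(path, config = cfg)
  expect_identical(back$variant, "perseclock")
  expect_identical(back$panel, m$panel)
  set.seed(15)
  x <- runif(input_length(cfg))
  expect_equal(forward(x, back), forward(x, m), tolerance = 1e-12)
  expect_error(read_clock_checkpoint(path, config = clock_config(channels = 12)),
               "conflicts")
})
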