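test_that("the no-padding shape algebra matches the reference stack", {
  spec <- cnn_spec(classes = 744, feature_maps = c(32, 64, 64))
  shp <- cnn_shapes(spec)
  expect_equal(shp$layer,
               c("input", "conv1", "mp1", "conv2", "conv3", "mp2"))
  expect_equal(shp$height, c(32, 30, 15, 13, 11, 5))
  expect_equal(shp$width, c(64, 62, 31, 29, 27, 13))

  # every conv layer obeys M_l = M_{l-1} - P + 1
  conv_rows <- grep("conv", shp$layer)
  for (r in conv_rows) {
    expect_equal(shp$height[r], shp$height[r - 1] - 3 + 1)
    expect_equal(shp$width[r], shp$width[r - 1] - 3 + 1)
  }

  # a single conv layer drops the second pooling stage
  shp1 <- cnn_shapes(cnn_spec(classes = 5, feature_maps = 16))
  expect_equal(shp1$layer, c("input", "conv1", "mp1"))
  m1 <- build_cnn(cnn_spec(classes = 5, feature_maps = 16), seed = 1)
  expect_false(any(vapply(m1$layers, function(l) l$name, "") == "mp2"))

  expect_error(cnn_shapes(cnn_spec(classes = 2, input_height = 4,
                                   input_width = 4,
                                   feature_maps = c(4, 4, 4, 4, 4))),
               "non-positive")
  expect_error(cnn_shapes(cnn_spec(classes = 2, input_height = 2,
                                   input_width = 2, kernel = c(3, 3),
                                   feature_maps = 4)),
               "non-positive")
})

test_that("the temporal-kernel ablation preserves image height", {
  spec <- tcnn_spec(classes = 10, feature_maps = c(8, 8, 8))
  shp <- cnn_shapes(spec)
  expect_equal(shp$height, rep(32, 6))
  expect_equal(shp$width, c(64, 62, 31, 29, 27, 13))
  sq <- cnn_spec(classes = 10, feature_maps = c(8, 8, 8))
  expect_false(count_parameters(spec) == count_parameters(sq))
})

test_that("parameter counting sums kernels, weights and biases", {
  # single fully connected 1024 -> 744 with bias
  expect_equal(1024 * 744 + 744, 762600)
  # single 3x3 conv, 2 -> 32 maps with bias
  expect_equal((3 * 3 * 2 + 1) * 32, 608)
  spec <- cnn_spec(classes = 744, feature_maps = c(32, 64, 64))
  expect_equal(count_parameters(spec),
               608 + (9 * 32 + 1) * 64 + (9 * 64 + 1) * 64 +
                 (5 * 13 * 64) * 1024 + 1024 + 762600)
  model <- build_cnn(cnn_spec(classes = 7, feature_maps = c(4, 6, 6),
                              fc1_width = 32), seed = 2)
  expect_equal(count_parameters(model), count_parameters(model$spec))
})

test_that("convolution plus ReLU matches a hand-computed evaluation", {
  # 4x4 single-channel input, one 3x3 kernel -> 2x2 pre-activation map
  spec <- cnn_spec(classes = 2, input_height = 4, input_width = 4,
                   channels = 1, feature_maps = 1, fc1_width = 2)
  model <- build_cnn(spec, seed = 5)
  set.seed(11)
  X <- array(rnorm(16), c(4, 4, 1, 1))
  conv <- model$layers[[1]]
  K <- matrix(conv$W, 3, 3)  # patch rows are column-major over the window
  out <- aegdi:::conv_forward(conv, X)$out
  for (oi in 1:2) for (oj in 1:2) {
    acc <- conv$b
    for (pa in 1:3) for (pb in 1:3) {
      acc <- acc + K[pa, pb] * X[oi + pa - 1, oj + pb - 1, 1, 1]
    }
    expect_equal(out[oi, oj, 1, 1], as.numeric(acc), tolerance = 1e-12)
  }
  # ReLU clamps the activation at zero
  act <- aegdi:::cnn_forward(model, X)
  expect_true(all(pmax(out, 0) >= 0))
})

test_that("initial weights are orthogonal", {
  model <- build_cnn(cnn_spec(classes = 6, feature_maps = c(8, 12, 12),
                              fc1_width = 64), seed = 3)
  for (l in model$layers) {
    if (l$type == "pool") next
    W <- l$W
    if (nrow(W) <= ncol(W)) {
      expect_lt(max(abs(tcrossprod(W) - diag(nrow(W)))), 1e-5)
    } else {
      expect_lt(max(abs(crossprod(W) - diag(ncol(W)))), 1e-5)
    }
  }
})

test_that("dropout is active only in training mode", {
  spec <- cnn_spec(classes = 3, input_height = 8, input_width = 8,
                   channels = 1, feature_maps = 4, fc1_width = 16)
  model <- build_cnn(spec, seed = 9)
  X <- array(rnorm(64), c(8, 8, 1, 1))
  p1 <- aegdi:::cnn_forward(model, X, train = FALSE)$probs
  p2 <- aegdi:::cnn_forward(model, X, train = FALSE)$probs
  expect_identical(p1, p2)
  set.seed(1)
  p3 <- aegdi:::cnn_forward(model, X, train = TRUE, dropout = 0.5)$probs
  expect_false(isTRUE(all.equal(p1, p3)))
  p4 <- aegdi:::cnn_forward(model, X, train = TRUE, dropout = 0)$probs
  expect_equal(p1, p4, tolerance = 1e-12)
})

test_that("predictions are normalized, reproducible and shape-checked", {
  spec <- cnn_spec(classes = 4, input_height = 14, input_width = 16,
                   channels = 2, feature_maps = c(3, 3, 3), fc1_width = 8)
  m1 <- build_cnn(spec, seed = 42)
  m2 <- build_cnn(spec, seed = 42)
  set.seed(6)
  X <- array(rnorm(14 * 16 * 2 * 5), c(14, 16, 2, 5))
  X[, , , 3] <- X[, , , 2]  # duplicated input row
  p <- predict(m1, X)
  expect_equal(dim(p), c(5L, 4L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_equal(p[2, ], p[3, ])
  expect_identical(p, predict(m2, X))  # untrained, same init seed
  expect_error(predict(m1, array(0, c(9, 16, 2, 1))), "expects")
})

test_that("training separates a separable toy problem and is seeded", {
  # two constant-angle image classes
  spec <- cnn_spec(classes = 2, input_height = 14, input_width = 16,
                   channels = 1, feature_maps = c(4, 4, 4), fc1_width = 8)
  n <- 40
  X <- array(0, c(14, 16, 1, n))
  y <- rep(1:2, each = n / 2)
  set.seed(3)
  for (i in seq_len(n)) {
    base <- if (y[i] == 1) 0.6 else 2.4
    X[, , 1, i] <- base + rnorm(14 * 16, sd = 0.05)
  }
  model <- build_cnn(spec, seed = 1)
  ts <- train_spec(epochs = 5, batch_size = 5, learning_rate = 0.01, seed = 2)
  fit <- train_cnn(model, X, y, ts)
  acc <- mean(apply(predict(fit, X), 1, which.max) == y)
  expect_equal(acc, 1.0)
  expect_length(fit$history, 5)

  # zero epochs: unchanged weights
  fit0 <- train_cnn(model, X, y, train_spec(epochs = 0))
  expect_identical(fit0$layers, model$layers)

  # same seed, same data: identical trajectory
  fit2 <- train_cnn(model, X, y, ts)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$layers[[1]]$W, fit2$layers[[1]]$W)

  expect_warning(train_cnn(model, X[, , , y == 1, drop = FALSE],
                           y[y == 1], train_spec(epochs = 1)),
                 "absent")
})

test_that("cycle aggregation fuses probabilities by their mean", {
  expect_equal(aggregate_cycles(rbind(c(0.2, 0.7, 0.1))), 2)
  unanimous <- matrix(rep(c(0.9, 0.1), 5), ncol = 2, byrow = TRUE)
  expect_equal(aggregate_cycles(unanimous), 1)
  two <- rbind(c(0.6, 0.4), c(0.1, 0.9))  # means 0.35 vs 0.65
  expect_equal(aggregate_cycles(two), 2)
  tie <- rbind(c(0.5, 0.5))
  expect_equal(aggregate_cycles(tie), 1)  # lowest index wins
  expect_equal(aggregate_cycles(two, method = "vote"), 1)  # 1-1 tie, lowest
  expect_error(aggregate_cycles(matrix(0, 0, 2)), "no probability")
})

test_that("models persist with their specification sidecar", {
  spec <- cnn_spec(classes = 3, input_height = 8, input_width = 8,
                   channels = 1, feature_maps = 4, fc1_width = 8)
  model <- build_cnn(spec, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_cnn(model, path)
  back <- load_cnn(path)
  X <- array(rnorm(64), c(8, 8, 1, 1))
  expect_identical(predict(back, X), predict(model, X))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n_params, count_parameters(model))
  unlink(c(path, paste0(path, ".json")))
})
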