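# frozen hand-derived values for the full-size architecture:
# 3438 -conv3-> 3436 -pool3-> 1145 -conv3-> 1143 -pool3-> 381 -conv3-> 379
# -pool3-> 126; 126 * 32 = 4032 flattened features
test_that("flattened size follows the valid-conv / floor-pool recurrence", {
  cfg <- model_config(n_classes = 2)
  expect_identical(flattened_size(3438, cfg), 4032L)

  small <- model_config(n_classes = 2, n_input = 27, kernel_sizes = 3,
                        descriptors = 8, pool_sizes = 3, hidden_sizes = 8)
  expect_identical(flattened_size(27, small), 64L)  # 27 -> 25 -> 8; 8 * 8

  expect_error(model_config(n_classes = 2, n_input = 2, kernel_sizes = 3,
                            descriptors = 4, pool_sizes = 3, hidden_sizes = 4),
               "architecture error")
})

test_that("parameter count matches the closed-form layer sum and the actual weights", {
  cfg <- model_config(n_classes = 2)
  # conv: k*c_in*c_out + c_out; dense: n_in*n_out + n_out
  by_hand <- (3 * 1 * 8 + 8) + (3 * 8 * 16 + 16) + (3 * 16 * 32 + 32) +
    (4032 * 256 + 256) + (256 * 128 + 128) + (128 * 64 + 64) + (64 * 2 + 2)
  expect_equal(n_parameters(cfg), by_hand)
  m <- build_model(cfg, seed = 1)
  expect_equal(length(unlist(m$params)), by_hand)
})

test_that("initialization is deterministic and the forward pass has the shape contract", {
  cfg <- toy_net_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 12)
  expect_false(identical(m1$params, m3$params))

  X <- matrix(rnorm(4 * 64), 4, 64)
  logits <- ramandelay:::cnn_forward_cpp(m1$params, ramandelay:::arch_list(cfg), X)
  expect_identical(dim(logits), c(4L, 2L))
  expect_error(model_config(n_classes = 1), "n_classes")
})

test_that("the C++ engine agrees with the double-precision R reference", {
  set.seed(42)
  cfg <- model_config(n_classes = 3, n_input = 30, kernel_sizes = c(3, 3),
                      descriptors = c(4, 6), pool_sizes = c(2, 2),
                      hidden_sizes = c(10, 7))
  m <- build_model(cfg, seed = 9)
  X <- matrix(rnorm(5 * 30), 5, 30)
  y <- c(0L, 1L, 2L, 1L, 0L)
  arch <- ramandelay:::arch_list(cfg)

  lg_cpp <- ramandelay:::cnn_forward_cpp(m$params, arch, X)
  lg_ref <- ref_forward(m$params, cfg, X)
  expect_equal(lg_cpp, lg_ref, tolerance = 1e-5)

  res <- ramandelay:::cnn_loss_grad_cpp(m$params, arch, X, y)
  expect_equal(res$loss, ref_ce_loss(m$params, cfg, X, y), tolerance = 1e-5)

  # analytic gradients vs central differences of the reference loss
  eps <- 1e-6
  for (nm in c("conv1_W", "conv2_b", "dense1_W", "dense3_b")) {
    p <- m$params[[nm]]
    idx <- seq_len(min(length(p), 20L))
    g_num <- vapply(idx, function(i) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- ref_ce_loss(pp, cfg, X, y)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- ref_ce_loss(pp, cfg, X, y)
      (lp - lm) / (2 * eps)
    }, numeric(1))
    scale <- max(abs(g_num), 1e-6)
    expect_lt(max(abs(g_num - res$gradients[[nm]][idx])) / scale, 1e-3)
  }
})

test_that("a separable toy problem reaches perfect training accuracy in budget", {
  set.seed(1)
  n <- 40
  X <- matrix(rnorm(n * 64), n, 64)
  y <- rep(0:1, each = n / 2)
  X[y == 1, ] <- X[y == 1, ] + 3  # constant offset between classes
  tr <- new_delay_dataset(X, y, c("a", "b"), seq_len(n))
  te <- new_delay_dataset(X[c(1:5, 36:40), ], y[c(1:5, 36:40)], c("a", "b"), 1:10)
  fit <- train_cnn(build_model(toy_net_config(), seed = 2), tr, te,
                   train_config(learning_rate = 3e-3, max_epochs = 300,
                                eval_interval = 10))
  expect_equal(max(fit$epoch_log$train_accuracy), 1)
  expect_equal(fit$final_accuracy, 1)
  # loss decreases apart from small oscillations between evaluations
  l <- fit$epoch_log$loss
  expect_true(all(diff(l) <= 0.05 * utils::head(l, -1) + 1e-8))
})

test_that("training bookkeeping follows the evaluation schedule", {
  X <- matrix(rnorm(12 * 64), 12, 64)
  y <- rep(0:1, 6)
  ds <- new_delay_dataset(X, y, c("a", "b"), 1:12)
  fit <- train_cnn(build_model(toy_net_config(), seed = 1), ds, ds,
                   train_config(learning_rate = 1e-3, max_epochs = 1,
                                eval_interval = 1))
  expect_identical(nrow(fit$epoch_log), 1L)
  expect_identical(fit$epoch_log$epoch, 1L)

  fit2 <- train_cnn(build_model(toy_net_config(), seed = 1), ds, ds,
                    train_config(learning_rate = 1e-3, max_epochs = 25,
                                 eval_interval = 10))
  expect_identical(fit2$epoch_log$epoch, c(10L, 20L, 25L))
  expect_identical(fit2$final_accuracy, max(fit2$epoch_log$test_accuracy))
})

test_that("accuracy on label-permuted test data stays at chance", {
  set.seed(7)
  n_te <- 120
  X <- matrix(rnorm((40 + n_te) * 64), 40 + n_te, 64)
  y_tr <- rep(0:1, 20)
  y_te <- sample(rep(0:1, n_te / 2))  # labels independent of features
  tr <- new_delay_dataset(X[1:40, ], y_tr, c("a", "b"), 1:40)
  te <- new_delay_dataset(X[41:(40 + n_te), ], y_te, c("a", "b"), 1:n_te)
  fit <- train_cnn(build_model(toy_net_config(), seed = 3), tr, te,
                   train_config(learning_rate = 1e-3, max_epochs = 60,
                                eval_interval = 20))
  band <- stats::qbinom(c(0.005, 0.995), n_te, 0.5) / n_te
  expect_gte(fit$final_accuracy, band[1])
  expect_lte(fit$final_accuracy, band[2])
})

test_that("the reported accuracy is invariant to test-set row order", {
  set.seed(5)
  X <- matrix(rnorm(30 * 64), 30, 64)
  y <- rep(0:2, 10)
  tr <- new_delay_dataset(X, y, c("a", "b", "c"), 1:30)
  fit <- function(te_order) {
    te <- new_delay_dataset(X[te_order, ], y[te_order], c("a", "b", "c"), te_order)
    train_cnn(build_model(toy_net_config(n_classes = 3), seed = 4), tr, te,
              train_config(learning_rate = 1e-3, max_epochs = 30,
                           eval_interval = 10))$final_accuracy
  }
  expect_identical(fit(1:30), fit(sample(30)))
})

test_that("regularization settings change training but not the shape contract", {
  cfg <- model_config(n_classes = 2, n_input = 64, kernel_sizes = c(3, 3),
                      descriptors = c(4, 8), pool_sizes = c(3, 3),
                      hidden_sizes = c(16, 8), dropout_p = 0.2, weight_decay = 1e-5)
  X <- matrix(rnorm(12 * 64), 12, 64)
  y <- rep(0:1, 6)
  ds <- new_delay_dataset(X, y, c("a", "b"), 1:12)
  fit <- train_cnn(build_model(cfg, seed = 1), ds, ds,
                   train_config(learning_rate = 1e-3, max_epochs = 5,
                                eval_interval = 5))
  expect_identical(dim(predict(fit, ds, type = "logits")), c(12L, 2L))
  probs <- predict(fit, ds, type = "prob")
  expect_equal(rowSums(probs), rep(1, 12), tolerance = 1e-6)
})

test_that("training rejects mismatched data", {
  X <- matrix(rnorm(8 * 64), 8, 64)
  ds <- new_delay_dataset(X, rep(0:1, 4), c("a", "b"), 1:8)
  wrong_width <- new_delay_dataset(X[, 1:32], rep(0:1, 4), c("a", "b"), 1:8)
  m <- build_model(toy_net_config(), seed = 1)
  expect_error(train_cnn(m, wrong_width, wrong_width, train_config()), "shape error")
  one_class <- new_delay_dataset(X, rep(0L, 8), c("a", "b"), 1:8)
  expect_error(train_cnn(m, one_class, ds, train_config()), "data error")
})
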