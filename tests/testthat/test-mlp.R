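test_that("initialization is seed-deterministic with the documented parameter count", {
  cfg <- mlp_config(seed = 7)
  a <- init_mlp(9, cfg)
  b <- init_mlp(9, cfg)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, init_mlp(9, mlp_config(seed = 8))$weights))

  # shape arithmetic oracle for the default topology, input d, 3 outputs
  d <- 9
  expected <- (d * 12 + 12) + (12 * 24 + 24) + (24 * 12 + 12) +
    (12 * 24 + 24) + (24 * 12 + 12) + (12 * 3 + 3)
  expect_equal(mlp_n_params(a), expected)

  expect_error(mlp_config(hidden_layers = integer(0)), "hidden layer")
  expect_error(mlp_config(dropout_rate = 1), "dropout")
})

test_that("backpropagation matches central finite differences on a tiny network", {
  # 2 -> 2 -> 3 network: (2*2+2) + (2*3+3) = 15 parameters
  cfg <- mlp_config(hidden_layers = 2, dropout_rate = 0, l1_lambda = 0.01,
                    l2_lambda = 0.02, seed = 3)
  model <- init_mlp(2, cfg)
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  y <- diag(3)[rep(1:3, 2), ]

  g <- eegmtc:::mlp_loss_grad(model$weights, model$biases, x, y,
                              l1 = cfg$l1_lambda, l2 = cfg$l2_lambda)
  eps <- 1e-6
  for (l in seq_along(model$weights)) {
    for (i in seq_along(model$weights[[l]])) {
      wp <- model$weights; wm <- model$weights
      wp[[l]][i] <- wp[[l]][i] + eps
      wm[[l]][i] <- wm[[l]][i] - eps
      fp <- eegmtc:::mlp_loss_grad(wp, model$biases, x, y, cfg$l1_lambda, cfg$l2_lambda)$loss
      fm <- eegmtc:::mlp_loss_grad(wm, model$biases, x, y, cfg$l1_lambda, cfg$l2_lambda)$loss
      fd <- (fp - fm) / (2 * eps)
      expect_lt(abs(g$g_w[[l]][i] - fd) / max(abs(fd), 1e-8), 1e-5)
    }
    for (i in seq_along(model$biases[[l]])) {
      bp <- model$biases; bm <- model$biases
      bp[[l]][i] <- bp[[l]][i] + eps
      bm[[l]][i] <- bm[[l]][i] - eps
      fp <- eegmtc:::mlp_loss_grad(model$weights, bp, x, y, cfg$l1_lambda, cfg$l2_lambda)$loss
      fm <- eegmtc:::mlp_loss_grad(model$weights, bm, x, y, cfg$l1_lambda, cfg$l2_lambda)$loss
      fd <- (fp - fm) / (2 * eps)
      expect_lt(abs(g$g_b[[l]][i] - fd) / max(abs(fd), 1e-8), 1e-5)
    }
  }
})

test_that("a separable 3-class toy set is fit perfectly with dropout off", {
  set.seed(10)
  n <- 20
  x <- rbind(cbind(rnorm(n, -3), rnorm(n, 0)),
             cbind(rnorm(n, 3), rnorm(n, 0)),
             cbind(rnorm(n, 0), rnorm(n, 4)))
  y <- rep(task_classes(), each = n)
  cfg <- mlp_config(hidden_layers = c(8, 8), dropout_rate = 0,
                    learning_rate = 0.01, seed = 1)
  model <- train_mlp(init_mlp(2, cfg), x, y, cfg)
  expect_equal(tail(model$history$accuracy, 1), 1.0)
  expect_lt(tail(model$history$loss, 1), head(model$history$loss, 1))
  expect_equal(nrow(model$history), cfg$epochs)
})

test_that("training is deterministic and dropout-off forward passes coincide", {
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3)
  y <- sample(task_classes(), 20, replace = TRUE)
  cfg <- mlp_config(hidden_layers = c(4, 4), epochs = 5, seed = 21)
  m1 <- train_mlp(init_mlp(3, cfg), x, y, cfg)
  m2 <- train_mlp(init_mlp(3, cfg), x, y, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)

  # with dropout 0 the stochastic training forward == deterministic predict
  cfg0 <- mlp_config(hidden_layers = 4, dropout_rate = 0, epochs = 1, seed = 2)
  m0 <- init_mlp(3, cfg0)
  fw_train <- eegmtc:::mlp_forward(m0$weights, m0$biases, x, masks = NULL)
  expect_equal(fw_train$probs, unname(predict_proba(m0, x)))
})

test_that("probabilities are normalized, symmetric at zero weights, consistent with predict", {
  cfg <- mlp_config(hidden_layers = c(5, 5), seed = 13)
  model <- init_mlp(4, cfg)
  set.seed(14)
  x <- matrix(rnorm(40), 10, 4)
  p <- predict_proba(model, x)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
  expect_equal(predict(model, x),
               task_classes()[apply(p, 1, which.max)])

  zero <- model
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  pz <- predict_proba(zero, x)
  expect_equal(unname(pz), matrix(1 / 3, 10, 3))
  # argmax ties break toward the lower canonical class index
  expect_equal(unique(predict(zero, x)), "left")
})

test_that("optimizer variants run and reduce the loss on the toy problem", {
  set.seed(15)
  x <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c("left", "word"), each = 10)
  for (opt in c("sgd", "sgd_momentum", "adam")) {
    cfg <- mlp_config(hidden_layers = 6, dropout_rate = 0, optimizer = opt,
                      learning_rate = 0.05, epochs = 30, seed = 3)
    m <- train_mlp(init_mlp(2, cfg), x, y, cfg)
    expect_lt(tail(m$history$loss, 1), head(m$history$loss, 1))
  }
})

test_that("dimension and label mismatches raise errors", {
  cfg <- mlp_config(hidden_layers = 3, epochs = 1, seed = 1)
  model <- init_mlp(4, cfg)
  expect_error(train_mlp(model, matrix(0, 5, 3), rep("left", 5)), "input_dim")
  expect_error(train_mlp(model, matrix(0, 5, 4), rep("up", 5)), "alphabet")
  expect_error(predict_proba(model, matrix(0, 2, 9)), "input_dim")
  expect_error(init_mlp(0, cfg), "input_dim")
})
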