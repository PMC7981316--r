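test_that("sigmoid has the defining properties and closed-form values", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.880797, tolerance = 1e-6)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(-x), 1 - sigmoid(x))
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_equal(sigmoid(1000), 1)  # saturates without overflow
})

test_that("forward pass matches hand evaluation", {
  set.seed(1)
  net <- nn_new(2, 1, hidden = 3, bias = FALSE)
  for (l in seq_along(net$weights)) net$weights[[l]][] <- 0
  act <- nn_forward(net, c(0.3, 0.7))
  expect_equal(act[[2]], rep(0.5, 3))
  expect_equal(act[[3]], 0.5)

  chain <- nn_new(1, 1, hidden = 1, bias = FALSE)
  chain$weights <- list(matrix(1), matrix(1))
  out <- nn_forward(chain, 0)[[3]]
  expect_equal(out, sigmoid(sigmoid(0)), tolerance = 1e-12)  # 0.62245...
  expect_equal(round(out, 4), 0.6225)
  expect_error(nn_forward(chain, c(1, 2)), "input length")
})

test_that("backprop deltas match central finite differences", {
  set.seed(42)
  for (rep in 1:6) {
    bias <- rep %% 2 == 0
    net <- nn_new(sample(3:6, 1), sample(1:2, 1),
                  hidden = sample(3:6, 1), alpha = 1, bias = bias)
    x <- runif(net$layer_sizes[1])
    y <- runif(rev(net$layer_sizes)[1])
    fd <- fd_gradient(net, x, y)
    up <- nn_backprop_step(net, x, y, alpha = 1)
    for (l in seq_along(net$weights)) {
      delta <- up$weights[[l]] - net$weights[[l]]   # = -grad at alpha 1
      rel <- abs(delta + fd[[l]]) / pmax(abs(fd[[l]]), 1e-6)
      expect_lt(max(rel), 1e-5)
    }
  }
})

test_that("zero error is a fixed point and updates are linear in alpha", {
  set.seed(7)
  net <- nn_new(3, 1, hidden = 2)
  x <- runif(3)
  y <- nn_forward(net, x)[[3]]   # target equals current output
  up <- nn_backprop_step(net, x, y)
  expect_equal(up$weights, net$weights)

  y2 <- 0.9
  d1 <- nn_backprop_step(net, x, y2, alpha = 0.3)
  d2 <- nn_backprop_step(net, x, y2, alpha = 0.6)
  for (l in seq_along(net$weights)) {
    expect_equal(2 * (d1$weights[[l]] - net$weights[[l]]),
                 d2$weights[[l]] - net$weights[[l]], tolerance = 1e-12)
  }
  expect_error(nn_backprop_step(net, x, y2, alpha = 0), "alpha")
})

test_that("compiled training loop reproduces R-level online updates", {
  set.seed(3)
  net <- nn_new(4, 2, hidden = 3, alpha = 0.4)
  X <- matrix(runif(28), nrow = 7)
  Y <- matrix(runif(14), nrow = 7)
  ord <- sample.int(7)
  ref <- net
  for (i in ord) ref <- nn_backprop_step(ref, X[i, ], Y[i, ])
  out <- igmnet:::cpp_nn_train(net$weights, X, Y, net$alpha, 1L, 0,
                               net$bias, matrix(ord, ncol = 1))
  expect_equal(out$weights, ref$weights, tolerance = 1e-14)
})

test_that("training solves XOR and is deterministic under a fixed seed", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 1, 1, 0)
  set.seed(42)
  fit <- nn_train(X, y, hidden = 2, alpha = 2, max_iterations = 2e5,
                  restarts = 5)
  pred <- nn_predict(fit, X)[, 1]
  expect_true(all((pred > 0.5) == (y == 1)))

  set.seed(99)
  f1 <- nn_train(X, y, hidden = 2, alpha = 1, max_iterations = 2e4)
  set.seed(99)
  f2 <- nn_train(X, y, hidden = 2, alpha = 1, max_iterations = 2e4)
  expect_identical(f1$weights, f2$weights)
})

test_that("training a constant 0.5 target drives the loss to ~0", {
  set.seed(8)
  X <- matrix(runif(40), nrow = 20)
  fit <- nn_train(X, rep(0.5, 20), hidden = 2, alpha = 0.5,
                  max_iterations = 4e4)
  expect_lt(fit$final_loss, 1e-3)
  expect_error(nn_train(X, rep(1.5, 20)), "\\[0, 1\\]")
})

test_that("k-fold splits are disjoint, exhaustive and balanced", {
  set.seed(2)
  f <- kfold_split(100, 10)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(tabulate(f, 10) == 10))

  f2 <- kfold_split(103, 10)
  expect_equal(sort(tabulate(f2, 10)), c(rep(10, 7), rep(11, 3)))

  # stratification balances labels across folds where possible
  strata <- rep(c("a", "b"), c(40, 60))
  f3 <- kfold_split(100, 10, strata = strata)
  expect_true(all(tabulate(f3, 10) == 10))
  expect_true(all(table(strata, f3)["a", ] == 4))

  expect_error(kfold_split(5, 6), "k <= n")
  # leave-one-out degenerate case
  f4 <- kfold_split(8, 8)
  expect_equal(sort(tabulate(f4, 8)), rep(1, 8))
})

test_that("cross-validation covers each probe once and is honest on null", {
  set.seed(13)
  n <- 150
  X <- matrix(runif(n * 3), nrow = n)
  y <- runif(n, 0.2, 0.8)               # independent of X
  cv <- nn_cross_validate(X, y, k = 10, hidden = 2, alpha = 0.3,
                          max_iterations = 2e4)
  expect_false(anyNA(cv$pred))
  expect_equal(length(cv$fold_mse), 10)
  # out-of-fold error approximates the target variance
  expect_gt(cv$mse, 0.6 * var(y))
  expect_lt(cv$mse, 1.8 * var(y))

  # perfectly learnable linearly separable labels -> near-zero error
  z <- as.numeric(X[, 1] + X[, 2] > 1)
  cv2 <- nn_cross_validate(X, z, k = 10, hidden = 3, alpha = 1,
                           max_iterations = 6e4)
  expect_lt(mean((cv2$pred[, 1] > 0.5) != z), 0.1)
})

test_that("min-max scaling maps columns into [0,1]", {
  X <- cbind(a = c(3, 7, 11), b = c(5, 5, 5))
  s <- minmax_scale(X)
  expect_equal(s[, "a"], c(0, 0.5, 1))
  expect_equal(s[, "b"], c(0, 0, 0))
})
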