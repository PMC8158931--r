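test_that("forward pass matches hand-computed matrix chains", {
  # identity network is the identity on nonnegative inputs
  id <- manual_mlpnn(list(diag(2), diag(2)), list(rep(0, 2), rep(0, 2)))
  expect_equal(unname(predict(id, matrix(c(1, 2), 1))), matrix(c(1, 2), 1))

  # ReLU clamps a negative hidden value, leaving only the output bias
  clamp <- manual_mlpnn(list(matrix(-1), matrix(1)),
                        list(0, 0.7))
  expect_equal(unname(predict(clamp, matrix(5))), matrix(0.7))

  # random 2 -> 3 -> 2 network against explicit arithmetic
  set.seed(99)
  W1 <- matrix(rnorm(6), 2, 3); b1 <- rnorm(3)
  W2 <- matrix(rnorm(6), 3, 2); b2 <- rnorm(2)
  net <- manual_mlpnn(list(W1, W2), list(b1, b2))
  x <- matrix(rnorm(8), 4, 2)
  want <- sweep(pmax(sweep(x %*% W1, 2, b1, "+"), 0) %*% W2, 2, b2, "+")
  expect_equal(unname(predict(net, x)), want, tolerance = 1e-10)

  expect_error(predict(net, matrix(1, 1, 5)), "features")
})

test_that("output-layer scaling scales predictions linearly", {
  set.seed(4)
  W1 <- matrix(rnorm(6), 2, 3); b1 <- rnorm(3)
  W2 <- matrix(rnorm(3), 3, 1); b2 <- rnorm(1)
  net <- manual_mlpnn(list(W1, W2), list(b1, b2))
  net3 <- manual_mlpnn(list(W1, 3 * W2), list(b1, 3 * b2))
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(net3, x), 3 * predict(net, x), tolerance = 1e-12)
})

test_that("loss is MSE plus lambda times summed squared Frobenius norms", {
  y <- matrix(c(0, 1, 2, 3), 2)
  expect_equal(mlpnn_loss(y, y), 0)
  expect_equal(mlpnn_loss(matrix(0), matrix(1)), 1)
  W <- list(matrix(c(1, 0, 2, 1), 2, 2))
  expect_equal(mlpnn_loss(y, y, W, 0.1), 0.6)
  expect_error(mlpnn_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("training reduces loss and restores the best validation epoch", {
  set.seed(5)
  x <- matrix(rnorm(120 * 6), 120, 6)
  B <- matrix(rnorm(6 * 3), 6, 3)
  y <- x %*% B + matrix(rnorm(120 * 3, 0, 0.05), 120, 3)
  fit <- mlpnn(x, y, hyperparams(1, 16, 1e-4, 0.1), seed = 2,
               control = quick_ctrl(300))
  expect_lt(fit$history[nrow(fit$history), "train"], fit$history[1, "train"])
  # early-stopping contract: restored weights achieve the minimum
  # recorded validation loss, and training stops within patience of it
  expect_equal(fit$val_loss, min(fit$history[, "val"]))
  expect_identical(fit$best_epoch, unname(which.min(fit$history[, "val"])))
  expect_lte(nrow(fit$history), fit$best_epoch + fit$control$patience)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(6)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- matrix(rnorm(60 * 2), 60, 2)
  probe <- matrix(rnorm(10 * 4), 10, 4)
  f1 <- mlpnn(x, y, hyperparams(2, 8, 1e-3, 0.3), seed = 77,
              control = quick_ctrl(60))
  f2 <- mlpnn(x, y, hyperparams(2, 8, 1e-3, 0.3), seed = 77,
              control = quick_ctrl(60))
  expect_identical(predict(f1, probe), predict(f2, probe))
  f3 <- mlpnn(x, y, hyperparams(2, 8, 1e-3, 0.3), seed = 78,
              control = quick_ctrl(60))
  expect_false(identical(predict(f1, probe), predict(f3, probe)))
})

test_that("a linear variant approaches the least-squares optimum", {
  set.seed(8)
  x <- matrix(rnorm(150 * 5), 150, 5)
  B <- matrix(rnorm(5 * 2), 5, 2)
  y <- x %*% B + matrix(rnorm(150 * 2, 0, 0.05), 150, 2)
  ls_fit <- lm.fit(cbind(1, x), y)
  mse_opt <- mean(ls_fit$residuals^2)
  fit <- mlpnn(x, y, hyperparams(1, 16, 0, 0), activation = "linear",
               validation = list(x = x[1:30, ], y = y[1:30, ]),
               seed = 3, control = mlpnn_control(max_epochs = 1500,
                                                patience = 300))
  mse_net <- mean((y - predict(fit, x))^2)
  expect_lt(mse_net, 1.1 * mse_opt)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2); y <- matrix(rnorm(10), 10, 1)
  expect_error(mlpnn(x, y[1:5, , drop = FALSE]), "same samples")
  expect_error(mlpnn(x, y, validation = list(x = x[0, , drop = FALSE],
                                             y = y[0, , drop = FALSE])),
               "empty validation")
  y_bad <- y; y_bad[3] <- NaN
  expect_error(mlpnn(x, y_bad, hyperparams(1, 8, 1e-3, 0.1),
                     control = quick_ctrl(50), seed = 1),
               "non-finite loss at epoch")
})

test_that("serialization round-trips bit-exactly", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("m1", "m2")))
  fit <- mlpnn(x, y, hyperparams(1, 4, 1e-3, 0.1), seed = 1,
               control = quick_ctrl(40))
  dir <- withr::local_tempdir()
  save_mlpnn(fit, dir)
  back <- load_mlpnn(dir)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$biases, fit$biases)
  expect_identical(back$input_ids, fit$input_ids)
  expect_identical(predict(back, x), predict(fit, x))
})
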