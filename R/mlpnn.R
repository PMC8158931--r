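#' Hyperparameter set for the metabolome-prediction network
#'
#' @param n_layers number of hidden layers (the tuning grid uses 1-3).
#' @param layer_size perceptrons per hidden layer (grid: 32, 128, 512).
#' @param l2_lambda L2 penalty weight on the layer weight matrices.
#' @param dropout dropout rate applied to hidden activations during
#'   training, in `[0, 1)`.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(n_layers = 1L, layer_size = 32L,
                        l2_lambda = 1e-3, dropout = 0.1) {
  stopifnot(n_layers >= 1, layer_size >= 1, l2_lambda >= 0,
            dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 layer_size = as.integer(layer_size),
                 l2_lambda = l2_lambda, dropout = dropout),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf("hyperparams: %d hidden layer(s) x %d, lambda = %g, dropout = %g\n",
              x$n_layers, x$layer_size, x$l2_lambda, x$dropout))
  invisible(x)
}

hidden_sizes <- function(hp) rep(hp$layer_size, hp$n_layers)

#' Training control parameters
#'
#' @param learning_rate ADAM step size.
#' @param max_epochs maximum number of full passes over the training set.
#' @param patience epochs without validation-loss improvement before
#'   training stops (early stopping).
#' @param batch_size minibatch size; `NULL` uses the full batch for up to
#'   1024 training samples and 1024 otherwise.
#' @param beta1,beta2,epsilon ADAM moment decay rates and stabilizer.
#' @return a list of class `mlpnn_control`.
#' @export
mlpnn_control <- function(learning_rate = 1e-3, max_epochs = 2000L,
                          patience = 40L, batch_size = NULL,
                          beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(patience >= 1, max_epochs >= patience, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = batch_size,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "mlpnn_control")
}

glorot_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    s <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -s, s),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# deterministic inference pass: ReLU (or identity) on hidden layers,
# linear output, no dropout
mlp_forward <- function(weights, biases, x, activation = "relu") {
  L <- length(weights)
  h <- x
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      z <- sweep(h %*% weights[[l]], 2L, biases[[l]], "+")
      h <- if (activation == "relu") relu(z) else z
    }
  }
  sweep(h %*% weights[[L]], 2L, biases[[L]], "+")
}

#' Network loss: mean squared error plus L2 weight penalty
#'
#' The MSE term averages the squared error over both samples and output
#' dimensions; the penalty is `lambda` times the summed squared Frobenius
#' norms of the weight matrices (biases are not penalized).
#'
#' @param y,y_hat observed and predicted matrices of identical shape.
#' @param weights list of layer weight matrices.
#' @param l2_lambda penalty weight.
#' @return a single number.
#' @export
mlpnn_loss <- function(y, y_hat, weights = list(), l2_lambda = 0) {
  if (!identical(dim(as.matrix(y)), dim(as.matrix(y_hat))))
    stop("y and y_hat must have the same shape")
  mse <- mean((y - y_hat)^2)
  pen <- if (l2_lambda > 0 && length(weights))
    l2_lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  else 0
  mse + pen
}

#' Fit a multivariate feedforward regression network
#'
#' Trains a fully connected network mapping all microbial input features
#' to all metabolite outputs at once: ReLU hidden layers, linear output,
#' ADAM optimization of mean squared error with an L2 penalty on the
#' weight matrices, inverted dropout on hidden activations, and early
#' stopping on a held-out validation set (the weights of the best
#' validation epoch are restored).
#'
#' @param x numeric matrix (samples x input features) or
#'   [abundance_table]; transformed values are expected (CLR or relative).
#' @param y numeric matrix (samples x output features) or
#'   [abundance_table], same samples as `x`.
#' @param hp a [hyperparams] object (architecture, lambda, dropout).
#' @param validation either a fraction in (0, 1) of the rows of `x` held
#'   out at random for early stopping, or a list `list(x =, y =)` of
#'   explicit validation matrices.
#' @param activation `"relu"` (default) or `"linear"` for an
#'   all-linear variant (used e.g. to verify attribution scores against
#'   the exact Jacobian).
#' @param control a [mlpnn_control] list.
#' @param seed integer seed making initialization, validation split,
#'   dropout masks and minibatch order reproducible.
#' @return an object of class `mlpnn` with components `weights`,
#'   `biases`, `hp`, `activation`, `input_ids`, `output_ids`, `history`
#'   (per-epoch training/validation loss), `best_epoch` and
#'   `val_loss` (validation loss of the restored weights).
#' @seealso [predict.mlpnn()], [olden_scores()], [save_mlpnn()]
#' @export
mlpnn <- function(x, y, hp = hyperparams(), validation = 0.2,
                  activation = c("relu", "linear"),
                  control = mlpnn_control(), seed = NULL) {
  activation <- match.arg(activation)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same samples")
  if (!is.null(seed)) set.seed(seed)

  if (is.list(validation)) {
    vx <- as.matrix(validation$x); vy <- as.matrix(validation$y)
    tx <- x; ty <- y
  } else {
    stopifnot(validation > 0, validation < 1)
    n_val <- max(1L, round(nrow(x) * validation))
    if (n_val >= nrow(x)) stop("validation split leaves no training samples")
    idx <- sample.int(nrow(x), n_val)
    vx <- x[idx, , drop = FALSE]; vy <- y[idx, , drop = FALSE]
    tx <- x[-idx, , drop = FALSE]; ty <- y[-idx, , drop = FALSE]
  }
  if (nrow(vx) == 0L) stop("empty validation set")
  if (ncol(vx) != ncol(tx)) stop("validation x has wrong feature count")

  n <- nrow(tx); d <- ncol(tx); p <- ncol(ty)
  dims <- c(d, hidden_sizes(hp), p)
  L <- length(dims) - 1L
  par <- glorot_init(dims)
  W <- par$W; b <- par$b
  lambda <- hp$l2_lambda; drop_p <- hp$dropout
  keep <- 1 - drop_p

  bs <- control$batch_size %||% if (n <= 1024L) n else 1024L
  bs <- min(bs, n)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  step <- 0L
  lr <- control$learning_rate
  beta1 <- control$beta1; beta2 <- control$beta2; eps <- control$epsilon

  history <- matrix(NA_real_, control$max_epochs, 2,
                    dimnames = list(NULL, c("train", "val")))
  best_val <- Inf; best_W <- W; best_b <- b; best_epoch <- 0L; wait <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      xb <- tx[rows, , drop = FALSE]; yb <- ty[rows, , drop = FALSE]
      nb <- nrow(xb)

      # forward with inverted dropout on hidden activations
      A <- vector("list", L); Z <- vector("list", L - 1L)
      M <- vector("list", L - 1L)
      A[[1L]] <- xb
      if (L > 1L) {
        for (l in seq_len(L - 1L)) {
          z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
          a <- if (activation == "relu") relu(z) else z
          if (drop_p > 0) {
            mask <- matrix(stats::runif(length(a)) >= drop_p,
                           nrow(a), ncol(a))
            a <- a * mask / keep
            M[[l]] <- mask
          }
          Z[[l]] <- z
          A[[l + 1L]] <- a
        }
      }
      out <- sweep(A[[L]] %*% W[[L]], 2L, b[[L]], "+")

      # backward
      dOut <- 2 * (out - yb) / (nb * p)
      gW <- vector("list", L); gb <- vector("list", L)
      gW[[L]] <- crossprod(A[[L]], dOut) + 2 * lambda * W[[L]]
      gb[[L]] <- colSums(dOut)
      if (L > 1L) {
        dA <- dOut %*% t(W[[L]])
        for (l in rev(seq_len(L - 1L))) {
          dZ <- dA
          if (drop_p > 0) dZ <- dZ * M[[l]] / keep
          if (activation == "relu") dZ <- dZ * (Z[[l]] > 0)
          gW[[l]] <- crossprod(A[[l]], dZ) + 2 * lambda * W[[l]]
          gb[[l]] <- colSums(dZ)
          if (l > 1L) dA <- dZ %*% t(W[[l]])
        }
      }

      # ADAM update
      step <- step + 1L
      c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }

    train_loss <- mlpnn_loss(ty, mlp_forward(W, b, tx, activation), W, lambda)
    val_loss <- mlpnn_loss(vy, mlp_forward(W, b, vx, activation), W, lambda)
    if (!is.finite(train_loss) || !is.finite(val_loss))
      stop("non-finite loss at epoch ", epoch,
           "; reduce the learning rate or check the inputs")
    history[epoch, ] <- c(train_loss, val_loss)

    if (val_loss < best_val) {
      best_val <- val_loss; best_W <- W; best_b <- b
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }

  structure(list(
    weights = lapply(best_W, unname),
    biases = lapply(best_b, unname),
    hp = hp, activation = activation,
    input_ids = colnames(x) %||% paste0("X", seq_len(d)),
    output_ids = colnames(y) %||% paste0("Y", seq_len(p)),
    history = history[!is.na(history[, 1]), , drop = FALSE],
    best_epoch = best_epoch, val_loss = best_val,
    control = control, seed = seed,
    train_means = list(x = colMeans(tx), y = colMeans(ty))
  ), class = "mlpnn")
}

#' @export
print.mlpnn <- function(x, ...) {
  dims <- c(length(x$input_ids),
            vapply(x$weights, ncol, integer(1)))
  cat("mlpnn:", paste(dims, collapse = " -> "),
      sprintf("(%s)\n", x$activation))
  cat(sprintf("  lambda = %g, dropout = %g; best epoch %d of %d, val loss %.5g\n",
              x$hp$l2_lambda, x$hp$dropout, x$best_epoch,
              nrow(x$history), x$val_loss))
  invisible(x)
}

#' Predict metabolite profiles from microbiome features
#'
#' Deterministic forward pass (dropout disabled). If `newdata` has column
#' names they are matched to the model's input features by name, so
#' column order does not matter.
#'
#' @param object a fitted [mlpnn] model.
#' @param newdata matrix or [abundance_table] of input features.
#' @param ... unused.
#' @return matrix of predictions, samples x output features.
#' @export
predict.mlpnn <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), object$input_ids)) {
    missing <- setdiff(object$input_ids, colnames(x))
    if (length(missing))
      stop("newdata lacks model input features: ",
           paste(utils::head(missing, 10), collapse = ", "))
    x <- x[, object$input_ids, drop = FALSE]
  }
  if (ncol(x) != length(object$input_ids))
    stop("newdata has ", ncol(x), " features; model expects ",
         length(object$input_ids))
  out <- mlp_forward(object$weights, object$biases, x, object$activation)
  colnames(out) <- object$output_ids
  rownames(out) <- rownames(x)
  out
}

#' @export
coef.mlpnn <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.mlpnn <- function(object, x, y, ...) {
  as.matrix(y) - predict(object, x)
}

#' Serialize / restore a trained network
#'
#' Writes one TSV per layer weight matrix and bias vector plus a JSON
#' manifest (shapes, hyperparameters, feature identifiers); values are
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param model a fitted [mlpnn].
#' @param dir directory to create/fill.
#' @return `dir` (save) or the restored `mlpnn` (load).
#' @export
save_mlpnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) apply(as.matrix(m), 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  for (l in seq_along(model$weights)) {
    writeLines(fmt(model$weights[[l]]),
               file.path(dir, sprintf("W%d.tsv", l)))
    writeLines(paste(sprintf("%.17g", model$biases[[l]]), collapse = "\t"),
               file.path(dir, sprintf("b%d.tsv", l)))
  }
  manifest <- list(
    n_layers_total = length(model$weights),
    dims = c(length(model$input_ids),
             vapply(model$weights, ncol, integer(1))),
    activation = model$activation,
    hyperparams = unclass(model$hp),
    input_ids = model$input_ids,
    output_ids = model$output_ids,
    best_epoch = model$best_epoch,
    val_loss = model$val_loss
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_mlpnn
#' @export
load_mlpnn <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  L <- man$n_layers_total
  read_mat <- function(f) {
    lines <- readLines(f)
    do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  }
  weights <- lapply(seq_len(L), function(l)
    read_mat(file.path(dir, sprintf("W%d.tsv", l))))
  biases <- lapply(seq_len(L), function(l)
    as.numeric(strsplit(readLines(file.path(dir, sprintf("b%d.tsv", l))),
                        "\t", fixed = TRUE)[[1]]))
  hp <- do.call(hyperparams, man$hyperparams)
  structure(list(
    weights = weights, biases = biases, hp = hp,
    activation = man$activation,
    input_ids = man$input_ids, output_ids = man$output_ids,
    history = NULL, best_epoch = man$best_epoch, val_loss = man$val_loss,
    control = NULL, seed = NULL, train_means = NULL
  ), class = "mlpnn")
}
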