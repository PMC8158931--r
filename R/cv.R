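#' Per-metabolite Spearman correlation
#'
#' Column-wise Spearman rank correlation between pooled test-set
#' predictions and observations. Ties get average ranks; a constant
#' column yields `NA`, which downstream means exclude.
#'
#' @param pred,obs matrices of identical shape (samples x metabolites).
#' @return named numeric vector of correlations, one per column.
#' @export
spearman_per_metabolite <- function(pred, obs) {
  pred <- as.matrix(pred); obs <- as.matrix(obs)
  if (!identical(dim(pred), dim(obs)))
    stop("pred and obs must have the same shape")
  if (nrow(pred) < 3L)
    stop("need at least 3 samples for a rank correlation")
  out <- vapply(seq_len(ncol(pred)), function(j) {
    suppressWarnings(stats::cor(pred[, j], obs[, j], method = "spearman"))
  }, numeric(1))
  names(out) <- colnames(obs)
  out
}

#' Iterated k-fold partitions
#'
#' @param n_samples number of samples.
#' @param k number of folds (near-equal sizes).
#' @param iterations number of independent random partitions.
#' @param seed master seed; each iteration uses a derived seed.
#' @return list of length `iterations`; each element an integer vector of
#'   fold labels in `1..k`, one per sample.
#' @export
make_partitions <- function(n_samples, k, iterations = 1L, seed = 1L) {
  if (k > n_samples) stop("k exceeds the number of samples")
  if (k < 2L) stop("k must be at least 2")
  lapply(seq_len(iterations), function(i) {
    set.seed(derive_seed(seed, "partition", i))
    sample(rep_len(seq_len(k), n_samples))
  })
}

lambda_grid <- function(n = 10L, from = 1e-4, to = 0.1) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Default hyperparameter search grid
#'
#' 1-3 hidden layers of size 32/128/512, ten log-spaced L2 penalties in
#' `[1e-4, 0.1]`, dropout in `{0.1, 0.3, 0.5}`.
#'
#' @return a data frame, one row per configuration.
#' @export
default_grid <- function() {
  expand.grid(n_layers = 1:3, layer_size = c(32L, 128L, 512L),
              l2_lambda = lambda_grid(), dropout = c(0.1, 0.3, 0.5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Random-search hyperparameter tuning by nested k-fold cross-validation
#'
#' Draws `n_trials` distinct configurations uniformly (without
#' replacement) from the grid; each is evaluated by k-fold
#' cross-validation on the supplied training partition, scoring the mean
#' Spearman correlation across metabolites of the pooled out-of-fold
#' predictions; the best-scoring configuration is returned.
#'
#' @param x,y training-partition matrices or [abundance_table]s.
#' @param grid data frame of candidate configurations (see
#'   [default_grid()]).
#' @param n_trials configurations to evaluate; if the grid is smaller the
#'   whole grid is used.
#' @param k folds of the nested cross-validation (default 5).
#' @param seed integer seed.
#' @param control a [mlpnn_control].
#' @return the winning [hyperparams], with the evaluation table in
#'   attribute `"trials"`.
#' @export
tune_hyperparameters <- function(x, y, grid = default_grid(),
                                 n_trials = 20L, k = 5L, seed = 1L,
                                 control = mlpnn_control()) {
  x <- as.matrix(x); y <- as.matrix(y)
  set.seed(derive_seed(seed, "tune"))
  rows <- if (nrow(grid) <= n_trials) seq_len(nrow(grid))
          else sample.int(nrow(grid), n_trials)
  folds <- make_partitions(nrow(x), k, 1L, derive_seed(seed, "tunefold"))[[1]]
  score <- numeric(length(rows))
  for (i in seq_along(rows)) {
    hp <- hyperparams(grid$n_layers[rows[i]], grid$layer_size[rows[i]],
                      grid$l2_lambda[rows[i]], grid$dropout[rows[i]])
    pooled <- matrix(NA_real_, nrow(x), ncol(y))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- mlpnn(x[!test, , drop = FALSE], y[!test, , drop = FALSE],
                   hp = hp, validation = 0.2, control = control,
                   seed = derive_seed(seed, "tunefit", i * 100L + f))
      pooled[test, ] <- predict(fit, x[test, , drop = FALSE])
    }
    scc <- spearman_per_metabolite(pooled, y)
    score[i] <- mean(scc, na.rm = TRUE)
  }
  best <- rows[which.max(score)]
  out <- hyperparams(grid$n_layers[best], grid$layer_size[best],
                     grid$l2_lambda[best], grid$dropout[best])
  attr(out, "trials") <- cbind(grid[rows, , drop = FALSE],
                               mean_scc = score)
  out
}

#' Iterated k-fold cross-validated training and evaluation
#'
#' For every iteration and fold: the fold's samples are held out as a
#' test set, the remainder is split 80/20 into training and
#' early-stopping validation sets, a network is fitted, and the held-out
#' samples are predicted. Test predictions are pooled within an
#' iteration before computing per-metabolite Spearman correlations, and
#' correlations are averaged across iterations.
#'
#' @param x,y aligned transformed tables or matrices
#'   (samples x microbes / samples x metabolites).
#' @param hp a [hyperparams] object, shared across all partitions; or a
#'   function `(train_x, train_y, seed)` returning one, to re-tune on
#'   every partition.
#' @param k folds per iteration (default 10).
#' @param iterations independent repetitions of the k-fold split
#'   (default 10).
#' @param seed master seed.
#' @param val_frac fraction of each training partition held out for
#'   early stopping (default 0.2).
#' @param control a [mlpnn_control].
#' @param keep_models keep all `iterations * k` fitted models (needed
#'   for attribution scores downstream); default `TRUE`.
#' @param train_y optional perturbed version of `y` (same shape) used
#'   for model fitting only, e.g. with injected noise; correlations are
#'   still scored against the clean `y`.
#' @return an object of class `micromet_cv`: `scc`
#'   (iterations x metabolites matrix), `mean_scc` (named vector,
#'   `NA` correlations excluded), `predictions` (per-iteration pooled
#'   prediction matrices), `models`, `partitions`, `hp`, `seed`.
#' @export
run_cv <- function(x, y, hp, k = 10L, iterations = 10L, seed = 1L,
                   val_frac = 0.2, control = mlpnn_control(),
                   keep_models = TRUE, train_y = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must share samples; align first")
  ty_all <- if (is.null(train_y)) y else as.matrix(train_y)
  if (!identical(dim(ty_all), dim(y)))
    stop("train_y must match the shape of y")
  parts <- make_partitions(nrow(x), k, iterations, seed)
  scc <- matrix(NA_real_, iterations, ncol(y),
                dimnames = list(NULL, colnames(y)))
  preds <- vector("list", iterations)
  models <- if (keep_models) vector("list", iterations * k) else NULL
  tuned_hp <- NULL
  for (i in seq_len(iterations)) {
    folds <- parts[[i]]
    pooled <- matrix(NA_real_, nrow(x), ncol(y),
                     dimnames = dimnames(y))
    for (f in seq_len(k)) {
      test <- folds == f
      fit_seed <- derive_seed(seed, "cvfit", i * 1000L + f)
      hp_f <- if (is.function(hp)) {
        hp(x[!test, , drop = FALSE], y[!test, , drop = FALSE], fit_seed)
      } else hp
      fit <- mlpnn(x[!test, , drop = FALSE], ty_all[!test, , drop = FALSE],
                   hp = hp_f, validation = val_frac,
                   control = control, seed = fit_seed)
      pooled[test, ] <- predict(fit, x[test, , drop = FALSE])
      if (keep_models) models[[(i - 1L) * k + f]] <- fit
      if (is.null(tuned_hp)) tuned_hp <- hp_f
    }
    preds[[i]] <- pooled
    scc[i, ] <- spearman_per_metabolite(pooled, y)
  }
  n_na <- sum(is.na(scc))
  if (n_na > 0)
    message(n_na, " constant-prediction SCC value(s) recorded as NA ",
            "and excluded from means")
  structure(list(
    scc = scc,
    mean_scc = colMeans(scc, na.rm = TRUE),
    predictions = preds, models = models, partitions = parts,
    hp = tuned_hp, k = k, iterations = iterations, seed = seed
  ), class = "micromet_cv")
}

#' @export
print.micromet_cv <- function(x, ...) {
  ms <- x$mean_scc[is.finite(x$mean_scc)]
  cat(sprintf(
    "micromet_cv: %d iteration(s) of %d-fold CV, %d metabolites\n",
    x$iterations, x$k, ncol(x$scc)))
  cat(sprintf("  mean SCC across metabolites: %.4f (range %.4f to %.4f)\n",
              mean(ms), min(ms), max(ms)))
  invisible(x)
}
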