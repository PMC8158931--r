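#' Destroy the microbiome-metabolome pairing by shuffling samples
#'
#' The rows (samples) of each table are permuted by two independent
#' seeded permutations while the sample identifiers keep their original
#' order, so each feature's marginal distribution is unchanged but the
#' pairing between the two omics is destroyed.
#'
#' @param x,y aligned [abundance_table]s or matrices.
#' @param seed integer seed.
#' @return list with shuffled `x` and `y`.
#' @export
shuffle_pairing <- function(x, y, seed = 1L) {
  xm <- as.matrix(x); ym <- as.matrix(y)
  if (nrow(xm) != nrow(ym)) stop("tables must be aligned")
  set.seed(derive_seed(seed, "shuffle_x"))
  p1 <- sample.int(nrow(xm))
  set.seed(derive_seed(seed, "shuffle_y"))
  p2 <- sample.int(nrow(ym))
  xs <- xm[p1, , drop = FALSE]; rownames(xs) <- rownames(xm)
  ys <- ym[p2, , drop = FALSE]; rownames(ys) <- rownames(ym)
  if (inherits(x, "abundance_table")) xs <- replace_values(x, xs)
  if (inherits(y, "abundance_table")) ys <- replace_values(y, ys)
  list(x = xs, y = ys)
}

#' Shuffled-data background distribution of Spearman correlations
#'
#' Repeats cross-validated training on sample-shuffled data (pairing
#' destroyed, re-shuffled each iteration by default) and pools the
#' per-metabolite, per-iteration correlations into a null distribution.
#' The trained shuffled models are retained for the attribution null.
#'
#' @param x,y aligned transformed tables or matrices.
#' @param hp the [hyperparams] tuned on the real data (no separate
#'   tuning is done for shuffled data).
#' @param k,iterations folds and iterations of the shuffled
#'   cross-validation; `iterations * k` models are trained.
#' @param pct percentile of the pooled null correlations used as the
#'   well-predicted cutoff (default 95).
#' @param seed master seed.
#' @param reshuffle_each_iteration re-draw the shuffling for every
#'   iteration (default) or shuffle once.
#' @param control a [mlpnn_control].
#' @return an object of class `micromet_background`: `scc_pool` (vector
#'   of length metabolites x iterations), `cutoff`, `pct`, `models`,
#'   `n_models`.
#' @export
generate_background <- function(x, y, hp, k = 10L, iterations = 10L,
                                pct = 95, seed = 1L,
                                reshuffle_each_iteration = TRUE,
                                control = mlpnn_control()) {
  xm <- as.matrix(x); ym <- as.matrix(y)
  pool <- numeric(0)
  models <- list()
  sh <- shuffle_pairing(xm, ym, derive_seed(seed, "bg", 0L))
  for (i in seq_len(iterations)) {
    if (reshuffle_each_iteration)
      sh <- shuffle_pairing(xm, ym, derive_seed(seed, "bg", i))
    cv <- run_cv(sh$x, sh$y, hp, k = k, iterations = 1L,
                 seed = derive_seed(seed, "bgcv", i),
                 control = control, keep_models = TRUE)
    pool <- c(pool, as.numeric(cv$scc[1L, ]))
    models <- c(models, cv$models)
  }
  pool_ok <- pool[is.finite(pool)]
  structure(list(
    scc_pool = pool,
    cutoff = wellpredicted_cutoff(pool_ok, pct),
    pct = pct, models = models, n_models = length(models),
    k = k, iterations = iterations, seed = seed
  ), class = "micromet_background")
}

#' @export
print.micromet_background <- function(x, ...) {
  cat(sprintf(
    "micromet_background: %d null models, pool of %d SCC values\n",
    x$n_models, length(x$scc_pool)))
  cat(sprintf("  %gth-percentile well-predicted cutoff: %.4f\n",
              x$pct, x$cutoff))
  invisible(x)
}

#' Well-predicted cutoff from a null correlation pool
#'
#' @param pool numeric vector of null Spearman correlations.
#' @param pct percentile (default 95); linear interpolation between
#'   order statistics.
#' @return the cutoff value.
#' @export
wellpredicted_cutoff <- function(pool, pct = 95) {
  percentile(pool, pct)
}

#' Call well-predicted metabolites
#'
#' A metabolite is well-predicted when its mean cross-validated Spearman
#' correlation lies strictly above the background cutoff; `NA`
#' correlations are never called.
#'
#' @param mean_scc named vector of per-metabolite mean correlations.
#' @param cutoff background cutoff (see [wellpredicted_cutoff()]).
#' @return named logical vector.
#' @export
call_wellpredicted <- function(mean_scc, cutoff) {
  out <- !is.na(mean_scc) & mean_scc > cutoff
  names(out) <- names(mean_scc)
  out
}
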