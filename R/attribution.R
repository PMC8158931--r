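#' Olden connection-weight attribution scores
#'
#' Forms the signed microbe-to-metabolite attribution matrix of a
#' trained network as the ordered product of its layer weight matrices
#' (biases and activations are ignored). For a linear-activation network
#' this product is exactly the input-output Jacobian; with ReLU hidden
#' layers it is a heuristic connection-weight attribution.
#'
#' @param model a fitted [mlpnn].
#' @param wellpredicted_mask optional logical vector over the model's
#'   output features; only the `TRUE` columns (well-predicted
#'   metabolites) are retained.
#' @return matrix, input features x (retained) output features.
#' @export
olden_scores <- function(model, wellpredicted_mask = NULL) {
  S <- Reduce(`%*%`, model$weights)
  rownames(S) <- model$input_ids
  colnames(S) <- model$output_ids
  if (!is.null(wellpredicted_mask)) {
    if (length(wellpredicted_mask) != ncol(S))
      stop("mask length ", length(wellpredicted_mask),
           " does not match ", ncol(S), " output features")
    S <- S[, wellpredicted_mask, drop = FALSE]
  }
  S
}

#' Attribution significance threshold from shuffled-data models
#'
#' Averages the Olden matrices of the models trained on shuffled data,
#' flattens the mean matrix and takes its `pct`-th percentile (linear
#' interpolation). The percentile is taken over the signed values by
#' default; set `use_absolute = TRUE` for a threshold on magnitudes.
#'
#' @param shuffled_models list of [mlpnn] models from the background run.
#' @param wellpredicted_mask logical vector selecting output columns.
#' @param pct percentile, default 97.5.
#' @param use_absolute take the percentile of `|scores|` instead of the
#'   signed scores.
#' @return the threshold value.
#' @export
attribution_null_threshold <- function(shuffled_models,
                                       wellpredicted_mask = NULL,
                                       pct = 97.5, use_absolute = FALSE) {
  if (length(shuffled_models) == 0L) stop("no shuffled models supplied")
  S_sum <- NULL
  for (m in shuffled_models) {
    S <- olden_scores(m, wellpredicted_mask)
    S_sum <- if (is.null(S_sum)) S else S_sum + S
  }
  v <- as.numeric(S_sum / length(shuffled_models))
  if (use_absolute) v <- abs(v)
  percentile(v, pct)
}

#' Microbes with at least one significant attribution score
#'
#' @param S_bar mean attribution matrix (microbes x metabolites),
#'   pre-normalization scale.
#' @param threshold significance threshold (see
#'   [attribution_null_threshold()]).
#' @return integer vector of retained row indices, named by microbe.
#' @export
filter_significant_microbes <- function(S_bar, threshold) {
  row_max <- apply(abs(S_bar), 1L, max)
  keep <- which(row_max > threshold)
  if (length(keep) == 0L)
    stop(sprintf(
      "no microbe has |mean attribution| above the threshold %.4g (largest observed: %.4g)",
      threshold, max(row_max)))
  keep
}

#' Normalize and clip attribution matrices
#'
#' Divides every entry of every per-model attribution matrix by the
#' significance threshold and clips to `[-1, 1]`, so every significant
#' score carries equal magnitude; the mean matrix is recomputed from the
#' normalized per-model matrices.
#'
#' @param S_list list of per-model attribution matrices (same shape).
#' @param threshold positive significance threshold.
#' @param retained_microbes optional identifiers recorded alongside.
#' @return an object of class `attribution_set`: `S_list` (normalized),
#'   `S_bar`, `threshold`, `normalized = TRUE`, `retained_microbes`.
#' @export
normalize_and_clip <- function(S_list, threshold, retained_microbes = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  norm <- lapply(S_list, function(S) pmin(pmax(S / threshold, -1), 1))
  S_bar <- Reduce(`+`, norm) / length(norm)
  structure(list(
    S_list = norm, S_bar = S_bar, threshold = threshold,
    normalized = TRUE,
    retained_microbes = retained_microbes %||% rownames(S_bar)
  ), class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf(
    "attribution_set: %d model matrices, %d microbes x %d metabolites%s\n",
    length(x$S_list), nrow(x$S_bar), ncol(x$S_bar),
    if (isTRUE(x$normalized)) " (normalized, clipped to [-1, 1])" else ""))
  invisible(x)
}

#' Full attribution workflow from trained models
#'
#' Computes per-model Olden matrices restricted to well-predicted
#' metabolites, derives the significance threshold from the shuffled
#' background models, drops microbes with no significant mean score,
#' then normalizes and clips.
#'
#' @param cv_models list of models from the real-data cross-validation.
#' @param background_models list of models from the shuffled background.
#' @param wellpredicted_mask logical vector over metabolites.
#' @param pct threshold percentile, default 97.5.
#' @param use_absolute see [attribution_null_threshold()].
#' @return an `attribution_set` (see [normalize_and_clip()]).
#' @export
compute_attribution <- function(cv_models, background_models,
                                wellpredicted_mask, pct = 97.5,
                                use_absolute = FALSE) {
  if (!any(wellpredicted_mask))
    stop("no well-predicted metabolites; cannot compute attributions")
  S_list <- lapply(cv_models, olden_scores, wellpredicted_mask)
  threshold <- attribution_null_threshold(background_models,
                                          wellpredicted_mask,
                                          pct, use_absolute)
  if (threshold <= 0)
    stop(sprintf("non-positive attribution threshold (%.4g); ",
                 threshold),
         "consider use_absolute = TRUE")
  S_bar_raw <- Reduce(`+`, S_list) / length(S_list)
  keep <- filter_significant_microbes(S_bar_raw, threshold)
  S_list <- lapply(S_list, function(S) S[keep, , drop = FALSE])
  normalize_and_clip(S_list, threshold,
                     retained_microbes = rownames(S_bar_raw)[keep])
}
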