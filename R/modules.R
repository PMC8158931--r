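#' Agglomerative clustering of attribution-matrix rows or columns
#'
#' Euclidean distance, complete linkage, dendrogram cut to exactly `k`
#' clusters. Cluster labels are renumbered by dendrogram leaf order so
#' module 1 is the leftmost block.
#'
#' @param m numeric matrix.
#' @param axis cluster the rows or the columns.
#' @param k number of clusters, `2 <= k <=` items on the axis.
#' @return integer vector of cluster labels named by item.
#' @export
hier_cluster <- function(m, axis = c("rows", "columns"), k) {
  axis <- match.arg(axis)
  X <- if (axis == "rows") as.matrix(m) else t(as.matrix(m))
  if (k > nrow(X)) stop("k = ", k, " exceeds ", nrow(X), " items")
  if (k < 1L) stop("k must be positive")
  if (k == nrow(X)) {
    labs <- seq_len(nrow(X))
    names(labs) <- rownames(X) %||% as.character(labs)
    return(labs)
  }
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "complete")
  labs <- stats::cutree(hc, k = k)
  # renumber in leaf order
  leaf_first <- labs[hc$order]
  map <- integer(k)
  map[unique(leaf_first)] <- seq_len(k)
  labs <- map[labs]
  names(labs) <- rownames(X) %||% as.character(seq_along(labs))
  labs
}

#' Consensus (mean connectivity) matrix of a set of clusterings
#'
#' @param labelings list of cluster-label vectors over the same items.
#' @return symmetric matrix with unit diagonal; entry `(a, b)` is the
#'   fraction of labelings placing `a` and `b` in the same cluster.
#' @export
consensus_matrix <- function(labelings) {
  if (length(labelings) == 0L) stop("no labelings supplied")
  n <- length(labelings[[1]])
  nm <- names(labelings[[1]])
  M <- matrix(0, n, n)
  for (lab in labelings) {
    if (length(lab) != n || !identical(names(lab), nm))
      stop("labelings cover inconsistent item sets")
    M <- M + outer(lab, lab, `==`)
  }
  M <- M / length(labelings)
  dimnames(M) <- list(nm, nm)
  M
}

#' Area under the consensus-matrix CDF
#'
#' Riemann sum `A = sum_j (x_j - x_{j-1}) * phi(x_j)` over the grid
#' `x_j in {0.01, ..., 1.00}` with `x_0 = 0`, where `phi(x_j)` is the
#' proportion of consensus entries strictly less than `x_j` (diagonal
#' included by default). A near-binary consensus gives a stable area.
#'
#' @param M consensus matrix, entries in `[0, 1]`.
#' @param include_diagonal include the unit diagonal in the proportions.
#' @return the area, in `[0, 1]`.
#' @export
cdf_area <- function(M, include_diagonal = TRUE) {
  v <- if (include_diagonal) as.numeric(M)
       else as.numeric(M[row(M) != col(M)])
  xs <- seq(0.01, 1, by = 0.01)
  widths <- diff(c(0, xs))
  phi <- vapply(xs, function(x) mean(v < x), numeric(1))
  sum(widths * phi)
}

#' Select the cluster count from the CDF-area profile
#'
#' Computes the proportional area change
#' `Delta_k = (A(k) - A(k-1)) / A(k-1)` for `k >= 3` and returns the
#' largest `k` with `Delta_k` strictly above the threshold, falling back
#' to `k = 2` when none exceeds it. An undefined `Delta_k`
#' (`A(k-1) = 0`) is treated as not exceeding the threshold.
#'
#' @param areas named numeric vector of `A(k)` on a contiguous range of
#'   `k` starting at 2 (names are the k values).
#' @param delta_threshold default 0.025.
#' @return the selected integer `k`, with the `Delta_k` vector attached
#'   as attribute `"delta"`.
#' @export
select_k <- function(areas, delta_threshold = 0.025) {
  ks <- as.integer(names(areas))
  if (is.null(names(areas)) || any(is.na(ks)))
    stop("areas must be named by their k values")
  o <- order(ks); ks <- ks[o]; areas <- areas[o]
  if (ks[1] != 2L || any(diff(ks) != 1L))
    stop("areas must cover a contiguous k range starting at 2")
  delta <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-1]) {
    if (areas[i - 1] == 0) next  # undefined; cannot exceed threshold
    delta[i] <- (areas[i] - areas[i - 1]) / areas[i - 1]
  }
  exceeds <- which(!is.na(delta) & delta > delta_threshold)
  k_star <- if (length(exceeds)) ks[max(exceeds)] else 2L
  attr(k_star, "delta") <- stats::setNames(delta, ks)
  k_star
}

#' Consensus determination of microbe and metabolite module counts
#'
#' For each candidate `k`, every normalized per-model attribution matrix
#' is clustered (rows for microbes, columns for metabolites), the
#' consensus matrix over the models is formed, and its CDF area
#' computed; [select_k()] picks the count for each axis.
#'
#' @param S_list list of normalized attribution matrices (one per
#'   trained model).
#' @param k_range candidate cluster counts, default `2:20` (capped at
#'   the number of items on each axis).
#' @param delta_threshold proportional-area threshold, default 0.025.
#' @param include_diagonal see [cdf_area()].
#' @return an object of class `consensus_diagnostics`: per axis, the
#'   selected `k_star`, the `A(k)` and `Delta_k` profiles, and the
#'   consensus matrix at `k_star`.
#' @export
choose_module_counts <- function(S_list, k_range = 2:20,
                                 delta_threshold = 0.025,
                                 include_diagonal = TRUE) {
  if (length(S_list) == 0L) stop("no attribution matrices supplied")
  scan_axis <- function(axis) {
    n_items <- if (axis == "rows") nrow(S_list[[1]]) else ncol(S_list[[1]])
    if (n_items < 2L) stop("fewer than 2 items to cluster on ", axis)
    ks <- k_range[k_range <= n_items]
    if (length(ks) == 0L) stop("no feasible k in range on ", axis)
    # one dendrogram per matrix, cut at every k
    cuts <- lapply(S_list, function(S) {
      X <- if (axis == "rows") S else t(S)
      hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                          method = "complete")
      cutree_all <- stats::cutree(hc, k = ks)
      if (is.null(dim(cutree_all)))
        cutree_all <- matrix(cutree_all, ncol = 1L,
                             dimnames = list(rownames(X), NULL))
      cutree_all
    })
    nm <- rownames(if (axis == "rows") S_list[[1]] else t(S_list[[1]]))
    areas <- numeric(length(ks))
    M_by_k <- vector("list", length(ks))
    for (j in seq_along(ks)) {
      labelings <- lapply(cuts, function(cm)
        stats::setNames(cm[, j], nm))
      M <- consensus_matrix(labelings)
      M_by_k[[j]] <- M
      areas[j] <- cdf_area(M, include_diagonal)
    }
    names(areas) <- ks
    k_star <- select_k(areas, delta_threshold)
    list(k_star = as.integer(k_star),
         areas = areas, delta = attr(k_star, "delta"),
         consensus = M_by_k[[which(ks == as.integer(k_star))]])
  }
  rows <- scan_axis("rows")
  cols <- scan_axis("cols")
  structure(list(rows = rows, cols = cols,
                 k_range = k_range, delta_threshold = delta_threshold),
            class = "consensus_diagnostics")
}

#' @export
print.consensus_diagnostics <- function(x, ...) {
  cat(sprintf(
    "consensus_diagnostics: k* = %d (microbes/rows), %d (metabolites/columns)\n",
    x$rows$k_star, x$cols$k_star))
  invisible(x)
}

#' Bicluster the mean attribution matrix into modules
#'
#' Rows (microbes) and columns (metabolites) are clustered independently
#' with Euclidean complete-linkage clustering at the consensus-selected
#' counts; module identifiers follow dendrogram leaf order.
#'
#' @param S_bar normalized mean attribution matrix.
#' @param k1,k2 module counts for microbes (rows) and metabolites
#'   (columns).
#' @return an object of class `module_result`: named integer vectors
#'   `microbe_modules` and `metabolite_modules`, plus `k1` and `k2`.
#' @export
bicluster_mean <- function(S_bar, k1, k2) {
  structure(list(
    microbe_modules = hier_cluster(S_bar, "rows", k1),
    metabolite_modules = hier_cluster(S_bar, "columns", k2),
    k1 = as.integer(k1), k2 = as.integer(k2)
  ), class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf(
    "module_result: %d microbe module(s) over %d microbes, %d metabolite module(s) over %d metabolites\n",
    x$k1, length(x$microbe_modules),
    x$k2, length(x$metabolite_modules)))
  invisible(x)
}

#' Per-sample module feature values
#'
#' The feature value of a module in a sample is the mean (normalized)
#' abundance of the module's member features in that sample.
#'
#' @param t an [abundance_table] or matrix (samples x features),
#'   normalized (CLR or relative) as configured.
#' @param modules named integer vector mapping features to module ids.
#' @return matrix samples x modules.
#' @export
module_feature_values <- function(t, modules) {
  v <- as.matrix(t)
  missing <- setdiff(names(modules), colnames(v))
  if (length(missing))
    stop("module member(s) absent from the table: ",
         paste(utils::head(missing, 10), collapse = ", "))
  ids <- sort(unique(modules))
  out <- vapply(ids, function(m) {
    members <- names(modules)[modules == m]
    rowMeans(v[, members, drop = FALSE])
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v), paste0("module_", ids)))
  out
}

#' Module-module interaction edge list
#'
#' One edge per (microbe module, metabolite module) pair, scored by the
#' mean normalized attribution over the corresponding block of the mean
#' attribution matrix; the sign encodes the interaction direction. The
#' full edge list is always returned; the display list drops edges with
#' `|score|` below the display threshold.
#'
#' @param S_bar normalized mean attribution matrix.
#' @param modules a `module_result` (see [bicluster_mean()]).
#' @param display_threshold minimum `|score|` for the display list,
#'   default 0.25.
#' @return list with data frames `full` and `display`
#'   (`microbe_module`, `metabolite_module`, `score`).
#' @export
module_network <- function(S_bar, modules, display_threshold = 0.25) {
  mm <- modules$microbe_modules; tm <- modules$metabolite_modules
  pairs <- expand.grid(microbe_module = sort(unique(mm)),
                       metabolite_module = sort(unique(tm)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs$score <- mapply(function(a, b) {
    mean(S_bar[names(mm)[mm == a], names(tm)[tm == b], drop = FALSE])
  }, pairs$microbe_module, pairs$metabolite_module)
  list(full = pairs,
       display = pairs[abs(pairs$score) >= display_threshold, ,
                       drop = FALSE])
}

# Greedy maximum-overlap matching of candidate modules to reference
# modules: repeatedly pair the (candidate, reference) modules sharing
# the most members, without reusing either; returns the summed overlap.
match_score <- function(candidate, reference) {
  items <- intersect(names(candidate), names(reference))
  cand <- candidate[items]; ref <- reference[items]
  O <- table(cand, ref)
  total <- 0
  while (length(O) && any(O > 0)) {
    idx <- which(O == max(O), arr.ind = TRUE)[1, , drop = TRUE]
    total <- total + O[idx[1], idx[2]]
    O <- O[-idx[1], -idx[2], drop = FALSE]
  }
  as.numeric(total)
}

#' Select the final full-data model by module match scores
#'
#' Trains several candidate networks on the full dataset, biclusters
#' each candidate's normalized attribution matrix at the
#' consensus-selected module counts, scores each candidate by the number
#' of microbes plus metabolites that co-cluster consistently with the
#' reference modules (greedy maximum-overlap matching of modules,
#' without reuse), and returns the highest-scoring candidate (ties go to
#' the lower candidate index).
#'
#' @param x,y full aligned transformed data.
#' @param hp tuned [hyperparams].
#' @param reference the `module_result` from the cross-validation
#'   models.
#' @param threshold the attribution normalization threshold.
#' @param wellpredicted_mask logical vector over metabolites.
#' @param n_candidates number of candidate models, default 10.
#' @param seed master seed.
#' @param val_frac early-stopping validation fraction per candidate.
#' @param control a [mlpnn_control].
#' @return list: `model` (the selected [mlpnn]), `scores` (combined
#'   match score per candidate), `index` (selected candidate),
#'   `modules` (the selected candidate's module assignments).
#' @export
select_final_model <- function(x, y, hp, reference, threshold,
                               wellpredicted_mask,
                               n_candidates = 10L, seed = 1L,
                               val_frac = 0.2,
                               control = mlpnn_control()) {
  x <- as.matrix(x); y <- as.matrix(y)
  scores <- numeric(n_candidates)
  fits <- vector("list", n_candidates)
  mods <- vector("list", n_candidates)
  for (i in seq_len(n_candidates)) {
    fit <- mlpnn(x, y, hp = hp, validation = val_frac, control = control,
                 seed = derive_seed(seed, "final", i))
    S <- olden_scores(fit, wellpredicted_mask)
    S <- S[reference_rows(reference, S), , drop = FALSE]
    S <- pmin(pmax(S / threshold, -1), 1)
    cand <- bicluster_mean(S, reference$k1, reference$k2)
    scores[i] <- match_score(cand$microbe_modules,
                             reference$microbe_modules) +
      match_score(cand$metabolite_modules, reference$metabolite_modules)
    fits[[i]] <- fit
    mods[[i]] <- cand
  }
  best <- which.max(scores)  # which.max returns the first maximum: tie rule
  list(model = fits[[best]], scores = scores, index = best,
       modules = mods[[best]])
}

reference_rows <- function(reference, S) {
  rows <- intersect(names(reference$microbe_modules), rownames(S))
  if (length(rows) < length(reference$microbe_modules))
    stop("candidate attribution matrix lacks reference microbes")
  rows
}
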