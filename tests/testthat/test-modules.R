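# naive agglomeration oracle: merge the two clusters with the smallest
# complete-linkage (maximum pairwise) distance, recording the partition
# at every cluster count
brute_complete_linkage <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  partitions
}

co_membership <- function(lab) outer(lab, lab, `==`)

test_that("hier_cluster agrees with a brute-force agglomeration oracle", {
  set.seed(14)
  X <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(paste0("r", 1:8), NULL))
  oracle <- brute_complete_linkage(X)
  for (k in 2:7) {
    got <- hier_cluster(X, "rows", k)
    expect_equal(co_membership(unname(got)), co_membership(oracle[[k]]),
                 info = paste("k =", k))
  }
})

test_that("hier_cluster recovers separated groups and handles edges", {
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 10, 0.1), 5, 2))
  rownames(X) <- paste0("p", 1:10)
  labs <- hier_cluster(X, "rows", 2)
  # groups recovered exactly (module ids are arbitrary labels)
  expect_equal(co_membership(unname(labs)),
               co_membership(rep(1:2, each = 5)))
  expect_equal(sort(unique(hier_cluster(X, "rows", 10))), 1:10)
  expect_error(hier_cluster(X, "rows", 11), "exceeds")
  # column axis clusters the transpose
  labs_c <- hier_cluster(t(X), "columns", 2)
  expect_equal(co_membership(unname(labs_c)),
               co_membership(rep(1:2, each = 5)))
})

test_that("consensus matrices average co-membership", {
  l1 <- c(a = 1, b = 1, c = 2)
  l2 <- c(a = 1, b = 2, c = 2)
  M <- consensus_matrix(list(l1, l2))
  expect_equal(diag(M), c(a = 1, b = 1, c = 1))
  expect_equal(M["a", "b"], 0.5)
  expect_equal(M["a", "c"], 0)
  expect_equal(M["b", "c"], 0.5)
  expect_equal(M, t(M))
  # identical labelings give a binary matrix
  Mb <- consensus_matrix(list(l1, l1, l1))
  expect_true(all(Mb %in% c(0, 1)))
  expect_error(consensus_matrix(list(l1, c(x = 1, y = 1, z = 2))),
               "inconsistent")
})

test_that("CDF area matches closed forms", {
  expect_equal(cdf_area(matrix(1, 4, 4)), 0)
  # binary consensus with zero-entry fraction p has area exactly p
  Mb <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(cdf_area(Mb), mean(Mb == 0))
  expect_equal(cdf_area(matrix(0.5, 3, 3)), 0.5)
})

test_that("select_k picks the largest k with a proportional gain > 2.5%", {
  A <- c(`2` = 0.20, `3` = 0.40, `4` = 0.41, `5` = 0.411)
  k <- select_k(A)
  expect_equal(as.integer(k), 3L)
  d <- attr(k, "delta")
  expect_equal(unname(d["3"]), 1)
  expect_equal(unname(d["4"]), 0.025)  # boundary: not strictly above

  doubling <- setNames(0.2 * 2^(0:8) / 2^8, 2:10)
  expect_equal(as.integer(select_k(doubling)), 10L)
  flat <- setNames(rep(0.4, 5), 2:6)
  expect_equal(as.integer(select_k(flat)), 2L)
  # zero previous area cannot exceed the threshold
  withzero <- c(`2` = 0, `3` = 0.5, `4` = 0.5)
  expect_equal(as.integer(select_k(withzero)), 2L)
  expect_error(select_k(c(`3` = 0.1, `4` = 0.2)), "starting at 2")
})

test_that("zero-noise planted blocks give binary consensus at the true k", {
  S_list <- lapply(1:10, function(i) make_block_S(0, 1))
  labelings <- lapply(S_list, function(S)
    hier_cluster(S, "rows", 3))
  M <- consensus_matrix(labelings)
  expect_true(all(M %in% c(0, 1)))
  expect_equal(cdf_area(M), mean(M == 0))
  # order of the matrices does not change the outcome
  cd1 <- choose_module_counts(S_list, k_range = 2:6)
  cd2 <- choose_module_counts(rev(S_list), k_range = 2:6)
  expect_identical(cd1$rows$k_star, cd2$rows$k_star)
  expect_identical(cd1$cols$areas, cd2$cols$areas)
})

test_that("biclustering recovers planted blocks exactly at zero noise", {
  skip_if_not_installed("mclust")
  S0 <- make_block_S(0, 1)
  mods <- bicluster_mean(S0, 3, 2)
  expect_equal(mclust::adjustedRandIndex(mods$microbe_modules,
                                         rep(1:3, each = 8)), 1)
  expect_equal(mclust::adjustedRandIndex(mods$metabolite_modules,
                                         rep(1:2, each = 10)), 1)
  # determinism
  expect_identical(mods, bicluster_mean(S0, 3, 2))
  # k = n gives singletons
  single <- bicluster_mean(S0, nrow(S0), 2)
  expect_equal(sort(unique(single$microbe_modules)), seq_len(nrow(S0)))
})

test_that("module feature values are member means", {
  v <- matrix(c(1, 3, 2, 4, 10, 20), 2, 3,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  mods <- c(f1 = 1L, f2 = 1L, f3 = 2L)
  mv <- module_feature_values(v, mods)
  expect_equal(mv[, "module_1"], c(s1 = 1.5, s2 = 3.5))
  expect_equal(mv[, "module_2"], c(s1 = 10, s2 = 20))
  # algebraic oracle: row-normalized membership indicator product
  ind <- sapply(1:2, function(m) (mods == m) / sum(mods == m))
  expect_equal(unname(mv), unname(v %*% ind))
  # singleton module is the feature's own column
  expect_equal(mv[, "module_2"], v[, "f3"])
  expect_error(module_feature_values(v[, 1:2], mods), "absent")
})

test_that("module networks average blocks and filter the display list", {
  S <- rbind(c(0.4, 0.4, 0.1), c(0.4, 0.4, 0.1), c(-0.6, -0.6, 0.05))
  dimnames(S) <- list(paste0("m", 1:3), paste0("t", 1:3))
  mods <- structure(list(
    microbe_modules = c(m1 = 1L, m2 = 1L, m3 = 2L),
    metabolite_modules = c(t1 = 1L, t2 = 1L, t3 = 2L),
    k1 = 2L, k2 = 2L), class = "module_result")
  net <- module_network(S, mods, display_threshold = 0.25)
  expect_equal(nrow(net$full), 4L)  # k1 x k2 edges
  e11 <- net$full$score[net$full$microbe_module == 1 &
                          net$full$metabolite_module == 1]
  expect_equal(e11, 0.4)
  e12 <- net$full$score[net$full$microbe_module == 1 &
                          net$full$metabolite_module == 2]
  expect_equal(e12, 0.1)
  expect_true(e11 %in% net$display$score)
  expect_false(e12 %in% net$display$score)
  # signs retained
  expect_true(any(net$display$score < 0))
})

test_that("final-model selection prefers the reference-matching candidate", {
  # perfect match dominates: score equals total item count
  ref <- structure(list(
    microbe_modules = c(a = 1L, b = 1L, c = 2L, d = 2L),
    metabolite_modules = c(x = 1L, y = 2L),
    k1 = 2L, k2 = 2L), class = "module_result")
  perfect <- micromet:::match_score(ref$microbe_modules,
                                    ref$microbe_modules) +
    micromet:::match_score(ref$metabolite_modules, ref$metabolite_modules)
  expect_equal(perfect, 6)
  # permuted labels still match perfectly
  perm <- c(a = 2L, b = 2L, c = 1L, d = 1L)
  expect_equal(micromet:::match_score(perm, ref$microbe_modules), 4)
  # partial match scores fewer members
  off <- c(a = 1L, b = 2L, c = 1L, d = 2L)
  expect_lt(micromet:::match_score(off, ref$microbe_modules), 4)
})

test_that("select_final_model trains candidates and applies the tie rule", {
  sim <- tiny_sim(seed = 8)
  mic <- clr_transform(sim$microbiome)
  met <- unclass(sim$metabolome)
  hp <- hyperparams(1, 8, 1e-3, 0.1)
  wp <- rep(TRUE, ncol(met))
  S_probe <- matrix(rnorm(ncol(mic) * ncol(met)), ncol(mic), ncol(met),
                    dimnames = list(colnames(mic), colnames(met)))
  ref <- bicluster_mean(S_probe, 2, 2)
  out <- select_final_model(mic, met, hp, ref, threshold = 0.5,
                            wellpredicted_mask = wp, n_candidates = 2,
                            seed = 3, control = quick_ctrl(40))
  expect_s3_class(out$model, "mlpnn")
  expect_length(out$scores, 2L)
  expect_equal(out$index, which.max(out$scores))
  # deterministic rerun selects the same candidate
  out2 <- select_final_model(mic, met, hp, ref, threshold = 0.5,
                             wellpredicted_mask = wp, n_candidates = 2,
                             seed = 3, control = quick_ctrl(40))
  expect_identical(out$scores, out2$scores)
})
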