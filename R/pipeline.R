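coerce_table <- function(t, omic) {
  if (inherits(t, "abundance_table")) return(t)
  if (is.character(t) && length(t) == 1L) return(read_abundance(t, omic))
  abundance_table(as.matrix(t), omic = omic, transform = "raw")
}

apply_transform <- function(t, transform, pseudocount, clr_denominator) {
  switch(transform,
         none = t,
         relative = relative_abundance(t),
         clr = clr_transform(t, pseudocount, clr_denominator))
}

#' Microbiome-to-metabolome integrative analysis
#'
#' Runs the full workflow on a paired dataset: sample alignment and
#' low-prevalence feature filtering; compositional transformation;
#' (optional) nested random hyperparameter search; iterated k-fold
#' cross-validated training of multivariate networks scored by
#' per-metabolite Spearman correlation; a shuffled-data background
#' distribution and its percentile cutoff for calling well-predicted
#' metabolites; signed microbe-metabolite attribution scores from the
#' trained network weights with a null-based significance threshold;
#' consensus determination of module counts and biclustering into
#' microbe and metabolite modules with a module-module interaction
#' network; and selection of a final full-data model by module match
#' scores.
#'
#' @param microbiome,metabolome [abundance_table]s, numeric matrices
#'   (samples x features) or file paths.
#' @param transform,metabolome_transform compositional transform for
#'   each table: `"clr"` (default), `"relative"` or `"none"`.
#' @param min_prevalence prevalence filter threshold (default 0.10).
#' @param pseudocount CLR pseudocount (default 1).
#' @param clr_denominator `"sum"` (default) or `"geometric_mean"`.
#' @param hp a [hyperparams] object; `NULL` triggers tuning by
#'   [tune_hyperparameters()] on the first training partition.
#' @param n_trials random-search configurations when tuning.
#' @param tune_mode `"once"` (default: hyperparameters from the first
#'   partition are shared) or `"every_partition"` (re-tuned for every
#'   fold; much slower).
#' @param k,iterations outer cross-validation folds and repetitions.
#' @param background_k,background_iterations shuffled-data
#'   cross-validation dimensions (default: same as the real run).
#' @param wellpredicted_pct background percentile for the well-predicted
#'   cutoff (default 95).
#' @param attribution_pct percentile for the attribution significance
#'   threshold (default 97.5).
#' @param attribution_absolute threshold on `|scores|` instead of signed
#'   scores.
#' @param k_range,delta_threshold consensus-clustering scan range and
#'   proportional-area threshold.
#' @param display_threshold minimum `|score|` for the display edge list.
#' @param n_candidates candidate final models (default 10).
#' @param seed master seed; every stage derives its own seed from it,
#'   so a rerun with the same configuration reproduces identical output.
#' @param control a [mlpnn_control].
#' @param outdir optional directory; when given, all result tables are
#'   written there (see Details).
#' @param verbose print stage progress.
#'
#' @details With `outdir` set the following files are written:
#'   `cv_scc.tsv`, `cv_predictions_iter<i>.tsv`, `background_scc.tsv`,
#'   `cutoff.json`, `attribution_mean.tsv`,
#'   `attribution_threshold.json`, `microbe_modules.tsv`,
#'   `metabolite_modules.tsv`, `module_edges_full.tsv`,
#'   `module_edges_display.tsv`, `consensus_diagnostics.tsv`,
#'   `manifest.json`, `run_log.txt`, and the final model under
#'   `final_model/`.
#'
#' @return an object of class `micromet` bundling the filtered
#'   transformed tables, `cv` ([run_cv()] result), `background`,
#'   `wellpredicted` (logical vector) and `cutoff`, `attribution`
#'   (`attribution_set`), `consensus` (`consensus_diagnostics`),
#'   `modules` (`module_result`), `network` (edge lists),
#'   `module_values` (per-sample module feature matrices), `final`
#'   (selected model and match scores), and `config`.
#' @export
micromet <- function(microbiome, metabolome,
                     transform = c("clr", "relative", "none"),
                     metabolome_transform = c("clr", "none"),
                     min_prevalence = 0.10, pseudocount = 1,
                     clr_denominator = c("sum", "geometric_mean"),
                     hp = NULL, n_trials = 20L,
                     tune_mode = c("once", "every_partition"),
                     k = 10L, iterations = 10L,
                     background_k = k, background_iterations = iterations,
                     wellpredicted_pct = 95, attribution_pct = 97.5,
                     attribution_absolute = FALSE,
                     k_range = 2:20, delta_threshold = 0.025,
                     display_threshold = 0.25,
                     n_candidates = 10L, seed = 1L,
                     control = mlpnn_control(), outdir = NULL,
                     verbose = TRUE) {
  transform <- match.arg(transform)
  metabolome_transform <- match.arg(metabolome_transform)
  clr_denominator <- match.arg(clr_denominator)
  tune_mode <- match.arg(tune_mode)
  say <- function(...) if (verbose) message(...)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    say(paste0(...))
  }

  note("loading and aligning tables")
  mic <- coerce_table(microbiome, "microbiome")
  met <- coerce_table(metabolome, "metabolome")
  al <- align_samples(mic, met)
  mic <- prevalence_filter(al$a, min_prevalence)
  met <- prevalence_filter(al$b, min_prevalence)
  note(sprintf("%d samples, %d microbes, %d metabolites after filtering",
               nrow(mic), ncol(mic), ncol(met)))
  mic_t <- apply_transform(mic, transform, pseudocount, clr_denominator)
  met_t <- apply_transform(met, metabolome_transform, pseudocount,
                           clr_denominator)

  if (is.null(hp)) {
    note("tuning hyperparameters on the first training partition")
    first <- make_partitions(nrow(mic_t), k, 1L, seed)[[1]]
    tr <- first != 1L
    hp <- tune_hyperparameters(unclass(mic_t)[tr, , drop = FALSE],
                               unclass(met_t)[tr, , drop = FALSE],
                               n_trials = n_trials,
                               seed = derive_seed(seed, "hp"),
                               control = control)
  }
  hp_cv <- if (tune_mode == "every_partition") {
    function(tx, ty, s) tune_hyperparameters(tx, ty, n_trials = n_trials,
                                             seed = s, control = control)
  } else hp

  note(sprintf("cross-validation: %d iteration(s) x %d fold(s)",
               iterations, k))
  cv <- run_cv(mic_t, met_t, hp_cv, k = k, iterations = iterations,
               seed = derive_seed(seed, "cv"), control = control)

  note(sprintf("background: %d iteration(s) x %d fold(s) on shuffled data",
               background_iterations, background_k))
  bg <- generate_background(mic_t, met_t, hp, k = background_k,
                            iterations = background_iterations,
                            pct = wellpredicted_pct,
                            seed = derive_seed(seed, "background"),
                            control = control)

  wp <- call_wellpredicted(cv$mean_scc, bg$cutoff)
  note(sprintf("well-predicted metabolites: %d of %d (cutoff %.4f)",
               sum(wp), length(wp), bg$cutoff))

  attribution <- NULL; consensus <- NULL; modules <- NULL
  network <- NULL; module_values <- NULL; final <- NULL
  if (sum(wp) >= 2L) {
    note("attribution scores and significance threshold")
    attribution <- tryCatch(
      compute_attribution(cv$models, bg$models, wp,
                          pct = attribution_pct,
                          use_absolute = attribution_absolute),
      error = function(e) {
        note("attribution skipped: ", conditionMessage(e)); NULL
      })
  } else {
    note("fewer than 2 well-predicted metabolites; module analysis skipped")
  }

  if (!is.null(attribution) && nrow(attribution$S_bar) >= 2L) {
    note("consensus clustering of attribution matrices")
    consensus <- choose_module_counts(attribution$S_list, k_range,
                                      delta_threshold)
    modules <- bicluster_mean(attribution$S_bar,
                              consensus$rows$k_star,
                              consensus$cols$k_star)
    network <- module_network(attribution$S_bar, modules,
                              display_threshold)
    module_values <- list(
      microbes = module_feature_values(mic_t, modules$microbe_modules),
      metabolites = module_feature_values(met_t,
                                          modules$metabolite_modules))
    note(sprintf("modules: %d microbe, %d metabolite",
                 modules$k1, modules$k2))
    note(sprintf("final model: %d candidate(s)", n_candidates))
    final <- select_final_model(mic_t, met_t, hp, modules,
                                attribution$threshold, wp,
                                n_candidates = n_candidates,
                                seed = derive_seed(seed, "candidates"),
                                control = control)
  }

  res <- structure(list(
    microbiome = mic_t, metabolome = met_t,
    cv = cv, background = bg,
    wellpredicted = wp, cutoff = bg$cutoff,
    attribution = attribution, consensus = consensus,
    modules = modules, network = network,
    module_values = module_values, final = final,
    config = list(
      transform = transform,
      metabolome_transform = metabolome_transform,
      min_prevalence = min_prevalence, pseudocount = pseudocount,
      clr_denominator = clr_denominator,
      hp = unclass(hp)[c("n_layers", "layer_size", "l2_lambda", "dropout")],
      tune_mode = tune_mode,
      k = k, iterations = iterations,
      background_k = background_k,
      background_iterations = background_iterations,
      wellpredicted_pct = wellpredicted_pct,
      attribution_pct = attribution_pct,
      attribution_absolute = attribution_absolute,
      k_range = range(k_range), delta_threshold = delta_threshold,
      display_threshold = display_threshold,
      n_candidates = n_candidates, seed = seed)
  ), class = "micromet")

  if (!is.null(outdir)) write_results(res, outdir, log_lines)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_results <- function(res, outdir, log_lines = character(0)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cv <- res$cv
  scc_df <- data.frame(metabolite = colnames(cv$scc),
                       t(cv$scc), check.names = FALSE)
  colnames(scc_df)[-1] <- paste0("iter_", seq_len(nrow(cv$scc)))
  scc_df$mean <- res$cv$mean_scc
  scc_df$wellpredicted <- res$wellpredicted
  write_tsv(scc_df, file.path(outdir, "cv_scc.tsv"))
  for (i in seq_along(cv$predictions)) {
    pred <- cv$predictions[[i]]
    write_tsv(data.frame(sample_id = rownames(pred), pred,
                         check.names = FALSE),
              file.path(outdir, sprintf("cv_predictions_iter%d.tsv", i)))
  }
  write_tsv(data.frame(scc = res$background$scc_pool),
            file.path(outdir, "background_scc.tsv"))
  jsonlite::write_json(
    list(percentile = res$background$pct, cutoff = res$cutoff,
         n_pool = length(res$background$scc_pool)),
    file.path(outdir, "cutoff.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$attribution)) {
    Sb <- res$attribution$S_bar
    write_tsv(data.frame(microbe = rownames(Sb), Sb, check.names = FALSE),
              file.path(outdir, "attribution_mean.tsv"))
    jsonlite::write_json(
      list(percentile = res$config$attribution_pct,
           threshold = res$attribution$threshold,
           n_retained_microbes = nrow(Sb)),
      file.path(outdir, "attribution_threshold.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$modules)) {
    write_tsv(data.frame(feature = names(res$modules$microbe_modules),
                         module = res$modules$microbe_modules),
              file.path(outdir, "microbe_modules.tsv"))
    write_tsv(data.frame(feature = names(res$modules$metabolite_modules),
                         module = res$modules$metabolite_modules),
              file.path(outdir, "metabolite_modules.tsv"))
    write_tsv(res$network$full, file.path(outdir, "module_edges_full.tsv"))
    write_tsv(res$network$display,
              file.path(outdir, "module_edges_display.tsv"))
    cd <- res$consensus
    diag_df <- rbind(
      data.frame(axis = "microbes", k = as.integer(names(cd$rows$areas)),
                 area = cd$rows$areas, delta = cd$rows$delta),
      data.frame(axis = "metabolites",
                 k = as.integer(names(cd$cols$areas)),
                 area = cd$cols$areas, delta = cd$cols$delta))
    write_tsv(diag_df, file.path(outdir, "consensus_diagnostics.tsv"))
  }
  if (!is.null(res$final))
    save_mlpnn(res$final$model, file.path(outdir, "final_model"))
  manifest <- list(
    package = "micromet",
    version = as.character(utils::packageVersion("micromet")),
    config = res$config,
    artifacts = list.files(outdir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.micromet <- function(x, ...) {
  cat("micromet analysis\n")
  cat(sprintf("  samples: %d  microbes: %d  metabolites: %d\n",
              nrow(x$microbiome), ncol(x$microbiome), ncol(x$metabolome)))
  ms <- x$cv$mean_scc[is.finite(x$cv$mean_scc)]
  cat(sprintf("  mean SCC: %.4f; cutoff: %.4f; well-predicted: %d (%.1f%%)\n",
              mean(ms), x$cutoff, sum(x$wellpredicted),
              100 * mean(x$wellpredicted)))
  if (!is.null(x$modules))
    cat(sprintf("  modules: %d microbe x %d metabolite (%d microbes retained)\n",
                x$modules$k1, x$modules$k2,
                length(x$modules$microbe_modules)))
  invisible(x)
}

#' @export
summary.micromet <- function(object, ...) {
  print(object)
  if (!is.null(object$network)) {
    cat("module-module edges (display list):\n")
    print(object$network$display, row.names = FALSE)
  }
  invisible(object)
}

#' Predict an external metabolome from a final model
#'
#' Applies the training transform to an external microbiome table whose
#' features are matched to the model inputs by name (order-corrected),
#' predicts the metabolome, and - when an observed external metabolome
#' is supplied - scores per-metabolite Spearman correlations.
#'
#' @param model a fitted [mlpnn] (e.g. `res$final$model`) or a directory
#'   written by [save_mlpnn()].
#' @param microbiome external [abundance_table], matrix or file path.
#' @param metabolome optional observed external metabolome.
#' @param transform,pseudocount,clr_denominator,min_prevalence the
#'   transform configuration used in training (defaults match
#'   [micromet()] defaults). The prevalence filter is not re-applied;
#'   features are selected by the model's input identifiers.
#' @param metabolome_transform transform for the observed metabolome.
#' @return list with `predictions` (samples x metabolites) and, when an
#'   observed metabolome is given, `scc` (per-metabolite Spearman
#'   correlation).
#' @export
predict_external <- function(model, microbiome, metabolome = NULL,
                             transform = c("clr", "relative", "none"),
                             metabolome_transform = c("clr", "none"),
                             pseudocount = 1,
                             clr_denominator = c("sum", "geometric_mean"),
                             min_prevalence = 0.10) {
  transform <- match.arg(transform)
  metabolome_transform <- match.arg(metabolome_transform)
  clr_denominator <- match.arg(clr_denominator)
  if (is.character(model)) model <- load_mlpnn(model)
  mic <- coerce_table(microbiome, "microbiome")
  missing <- setdiff(model$input_ids, feature_ids(mic))
  if (length(missing))
    stop("external microbiome lacks model features: ",
         paste(utils::head(missing, 10), collapse = ", "))
  mic_t <- apply_transform(mic, transform, pseudocount, clr_denominator)
  x <- unclass(mic_t)[, model$input_ids, drop = FALSE]
  pred <- predict(model, x)
  out <- list(predictions = pred)
  if (!is.null(metabolome)) {
    met <- coerce_table(metabolome, "metabolome")
    met_t <- apply_transform(met, metabolome_transform, pseudocount,
                             clr_denominator)
    obs <- unclass(met_t)[rownames(pred), model$output_ids, drop = FALSE]
    out$scc <- spearman_per_metabolite(pred, obs)
  }
  out
}
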