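# shared fixtures, all built in code

quick_ctrl <- function(max_epochs = 200L, patience = 40L)
  mlpnn_control(max_epochs = max_epochs,
                patience = min(patience, max_epochs))

# hand-built network, bypassing training
manual_mlpnn <- function(weights, biases, activation = "relu",
                         input_ids = NULL, output_ids = NULL) {
  structure(list(
    weights = weights, biases = biases,
    hp = hyperparams(length(weights) - 1L, ncol(weights[[1]]), 0, 0),
    activation = activation,
    input_ids = input_ids %||% paste0("X", seq_len(nrow(weights[[1]]))),
    output_ids = output_ids %||%
      paste0("Y", seq_len(ncol(weights[[length(weights)]]))),
    history = NULL, best_epoch = 0L, val_loss = NA_real_,
    control = NULL, seed = NULL, train_means = NULL
  ), class = "mlpnn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3 row blocks x 2 column blocks, block-constant +-1, additive noise
make_block_S <- function(sd, seed, rows_per_block = 8L,
                         cols_per_block = 10L) {
  set.seed(seed)
  base <- matrix(c(1, -1, -1, 1, 1, 1), 3, 2, byrow = TRUE)
  S <- base[rep(1:3, each = rows_per_block),
            rep(1:2, each = cols_per_block)]
  dimnames(S) <- list(paste0("m", seq_len(nrow(S))),
                      paste0("t", seq_len(ncol(S))))
  S + matrix(stats::rnorm(length(S), 0, sd), nrow(S), ncol(S))
}

# small strong-signal paired dataset for fast end-to-end tests
tiny_sim <- function(seed = 1L, n_samples = 50L, effect_size = 3,
                     noise_sd = 0.2) {
  simulate_paired(n_samples = n_samples, n_microbe_modules = 2L,
                  microbes_per_module = 5L, n_metabolite_modules = 2L,
                  metabolites_per_module = 5L, n_noise_metabolites = 5L,
                  effect_size = effect_size, noise_sd = noise_sd,
                  seed = seed)
}
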