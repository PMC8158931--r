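#' Simulate a paired microbiome-metabolome dataset with planted modules
#'
#' Microbial abundances follow a log-normal compositional model: each
#' microbe belongs to one module and loads on that module's latent
#' per-sample factor, creating correlated within-module blocks typical
#' of microbial communities. Each driven metabolite responds to exactly
#' one microbe module: its value is the planted sign times the effect
#' size times the module's mean CLR abundance (optionally passed through
#' a softplus nonlinearity), plus Gaussian noise. Pure-noise metabolites
#' are independent Gaussians. All metabolite columns are shifted to
#' nonnegative intensities. The planted structure is returned as ground
#' truth.
#'
#' @param n_samples number of samples.
#' @param n_microbe_modules,microbes_per_module planted microbe module
#'   structure.
#' @param n_metabolite_modules,metabolites_per_module planted driven
#'   metabolite blocks; metabolite module q is driven by microbe module
#'   `((q - 1) mod n_microbe_modules) + 1` with sign `+1` for odd q and
#'   `-1` for even q.
#' @param n_noise_metabolites metabolites carrying no microbial signal.
#' @param effect_size scale of the planted microbe-to-metabolite effect;
#'   0 makes every metabolite independent of the microbiome.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   driven metabolites.
#' @param nonlinear pass the driver signal through a monotone softplus
#'   nonlinearity.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list with `microbiome` and `metabolome` ([abundance_table]s,
#'   `transform = "raw"`) and `truth`, an object of class
#'   `synthetic_truth` recording module memberships, the module-pair
#'   sign matrix, drivers, `noise_sd` and `seed`.
#' @export
simulate_paired <- function(n_samples = 100L,
                            n_microbe_modules = 3L,
                            microbes_per_module = 10L,
                            n_metabolite_modules = 3L,
                            metabolites_per_module = 15L,
                            n_noise_metabolites = 20L,
                            effect_size = 2,
                            noise_sd = 0.5,
                            nonlinear = FALSE,
                            seed = 1L) {
  stopifnot(n_samples >= 1, n_microbe_modules >= 1,
            microbes_per_module >= 1, n_metabolite_modules >= 1,
            metabolites_per_module >= 1, n_noise_metabolites >= 0,
            effect_size >= 0, noise_sd >= 0)
  set.seed(derive_seed(seed, "simulate"))

  n_mic <- n_microbe_modules * microbes_per_module
  mic_module <- rep(seq_len(n_microbe_modules), each = microbes_per_module)
  mic_ids <- sprintf("microbe_%02d", seq_len(n_mic))
  names(mic_module) <- mic_ids

  # latent per-sample module factors -> correlated log-normal abundances
  z <- matrix(stats::rnorm(n_samples * n_microbe_modules),
              n_samples, n_microbe_modules)
  base <- stats::rnorm(n_mic, 0, 0.5)
  log_a <- sweep(z[, mic_module, drop = FALSE], 2L, base, "+") +
    matrix(stats::rnorm(n_samples * n_mic, 0, 0.5), n_samples, n_mic)
  microbiome <- exp(log_a)
  dimnames(microbiome) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                               mic_ids)

  # per-sample CLR (sum denominator) of the microbial table drives signals
  clr <- log(microbiome / rowSums(microbiome))
  driver_mean <- vapply(seq_len(n_microbe_modules), function(m)
    rowMeans(clr[, mic_module == m, drop = FALSE]),
    numeric(n_samples))
  # center each driver so the nonlinearity acts around 0 rather than in
  # the saturated tail of the log-proportion scale
  driver_mean <- scale(driver_mean, center = TRUE, scale = FALSE)

  n_driven <- n_metabolite_modules * metabolites_per_module
  met_module <- rep(seq_len(n_metabolite_modules),
                    each = metabolites_per_module)
  driver_of <- ((seq_len(n_metabolite_modules) - 1L) %%
                  n_microbe_modules) + 1L
  sign_of <- ifelse(seq_len(n_metabolite_modules) %% 2L == 1L, 1, -1)

  metabolome <- matrix(0, n_samples, n_driven + n_noise_metabolites)
  for (j in seq_len(n_driven)) {
    q <- met_module[j]
    signal <- effect_size * driver_mean[, driver_of[q]]
    if (nonlinear) signal <- softplus(signal)
    metabolome[, j] <- sign_of[q] * signal +
      stats::rnorm(n_samples, 0, noise_sd)
  }
  if (n_noise_metabolites > 0) {
    metabolome[, n_driven + seq_len(n_noise_metabolites)] <-
      stats::rnorm(n_samples * n_noise_metabolites)
  }
  # shift to nonnegative intensities (column minimum becomes 0)
  metabolome <- sweep(metabolome, 2L, apply(metabolome, 2L, min), "-")
  met_ids <- c(sprintf("metabolite_%03d", seq_len(n_driven)),
               if (n_noise_metabolites > 0)
                 sprintf("noise_%03d", seq_len(n_noise_metabolites)))
  dimnames(metabolome) <- list(rownames(microbiome), met_ids)

  met_module_full <- c(met_module, rep(0L, n_noise_metabolites))
  names(met_module_full) <- met_ids
  effect_sign <- matrix(0, n_microbe_modules, n_metabolite_modules,
                        dimnames = list(
                          paste0("microbe_module_", seq_len(n_microbe_modules)),
                          paste0("metabolite_module_",
                                 seq_len(n_metabolite_modules))))
  for (q in seq_len(n_metabolite_modules))
    effect_sign[driver_of[q], q] <- sign_of[q]
  if (effect_size == 0) effect_sign[] <- 0

  truth <- structure(list(
    microbe_module_of = mic_module,
    metabolite_module_of = met_module_full,
    driver_of_metabolite_module = driver_of,
    effect_sign = effect_sign,
    effect_size = effect_size, noise_sd = noise_sd,
    nonlinear = nonlinear, seed = seed
  ), class = "synthetic_truth")

  list(microbiome = abundance_table(microbiome, "microbiome", "raw"),
       metabolome = abundance_table(metabolome, "metabolome", "raw"),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d microbe module(s), %d driven metabolite module(s), %d noise metabolite(s)\n",
    max(x$microbe_module_of), max(x$metabolite_module_of),
    sum(x$metabolite_module_of == 0)))
  cat(sprintf("  effect size %g, noise sd %g, nonlinear: %s, seed %d\n",
              x$effect_size, x$noise_sd, x$nonlinear, x$seed))
  invisible(x)
}

#' Add i.i.d. Gaussian noise to a table
#'
#' Intended for real-valued (e.g. CLR-transformed) data; adding noise to
#' a raw/relative table that would create negative values is an error.
#'
#' @param y matrix or [abundance_table].
#' @param variance noise variance; 0 returns the input unchanged.
#' @param seed integer seed.
#' @return the perturbed object, same class as the input.
#' @export
add_gaussian_noise <- function(y, variance, seed = 1L) {
  stopifnot(variance >= 0)
  if (variance == 0) return(y)
  set.seed(derive_seed(seed, "noise"))
  v <- as.matrix(y)
  out <- v + matrix(stats::rnorm(length(v), 0, sqrt(variance)),
                    nrow(v), ncol(v))
  if (inherits(y, "abundance_table")) {
    if (attr(y, "transform") != "clr" && any(out < 0))
      stop("noise created negative raw/relative abundances; ",
           "transform (e.g. CLR) before adding noise")
    return(replace_values(y, out))
  }
  out
}
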