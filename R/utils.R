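#' @keywords internal
"_PACKAGE"

# Deterministic derivation of stage seeds from one master seed.
# Keeps every derived seed a valid 32-bit R integer.
derive_seed <- function(master, tag, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag))) %% 7919L
  val <- (as.double(master) * 48271 + h * 2654435.0 + index * 104729) %%
    2147483399
  as.integer(val) + 1L
}

# Percentile with linear interpolation between order statistics
# (stats::quantile type 7, the R default).
percentile <- function(x, pct) {
  if (length(x) == 0L) stop("empty vector: cannot take a percentile")
  if (any(!is.finite(x))) stop("non-finite values in percentile input")
  unname(stats::quantile(x, probs = pct / 100, type = 7))
}

relu <- function(z) {
  z[z < 0] <- 0
  z
}

softplus <- function(z) {
  # numerically stable log(1 + exp(z))
  pmax(z, 0) + log1p(exp(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
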