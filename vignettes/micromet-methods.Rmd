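---
title: "micromet: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{micromet: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`micromet` models the community metabolome of a sample as a multivariate
function of its microbiome profile and then mines the fitted networks
for interpretable microbe–metabolite structure. This vignette is the
package's account of the underlying statistics: what the model assumes,
which knobs matter, how the edge cases are handled, and where the
method's behaviour deviates from what one might naively expect.

## The regression model

The core estimator is a fully connected feedforward network fitted by
`mlpnn()`: ReLU hidden layers, a linear output layer predicting all
metabolites jointly, and the loss

$$\mathrm{Loss} = \frac{1}{N\,p}\sum_{i,j}(y_{ij}-\hat y_{ij})^2 +
\lambda \sum_l \lVert W_l\rVert_F^2 .$$

Two conventions deserve note. First, the mean squared error is averaged
over samples *and* output dimensions, so the loss scale — and with it a
given λ — does not drift with the size of the metabolome; the λ search
grid (ten log-spaced values in $[10^{-4}, 10^{-1}]$) spans enough range
to absorb this. Second, the penalty applies to weight matrices only,
never biases, matching the loss as written above.

Training uses full-batch ADAM (learning rate $10^{-3}$, default; the
batch caps at 1024 samples for larger cohorts), uniform Glorot
initialization from a seeded generator, and inverted dropout: hidden
activations are masked and rescaled by $1/(1-p)$ during training, so at
inference the stored weights are used exactly as learned. That last
point matters downstream — the attribution scores are formed from the
stored weights, and the inverted convention means no dropout correction
is needed there.

Early stopping monitors the validation loss after each epoch (a full
pass over the training data) and halts after 40 epochs without
improvement, restoring the weights of the best validation epoch. The
returned model therefore always attains the minimum recorded validation
loss — an invariant the test suite asserts on every training run it
performs. A non-finite loss aborts with the offending epoch index
rather than silently producing NaN weights.

## Compositional transforms

Microbiome profiles are compositional; the package's default transform
is a centered log-ratio with the *sum* of the (pseudocounted) entries as
the reference, i.e. a log-proportion:
$x_i \mapsto \log\!\big((x_i + c)\big/\sum_j (x_j + c)\big)$ with
pseudocount $c = 1$. The conventional geometric-mean reference is
available via `clr_transform(..., denominator = "geometric_mean")`; the
sum form is the default because it is the form the rest of the
workflow was designed around. The pseudocount applies to the values on
whatever scale the table holds (counts or relative abundances); both
are configurable. The prevalence filter (drop features present in
fewer than 10% of samples, "present" meaning strictly nonzero, with the
boundary case retained) runs before any transform.

One consequence of a shared per-sample denominator is worth spelling
out: applying the CLR to the *metabolome* couples every metabolite
through the common log-total. If a few strongly varying metabolites
dominate the total, every other metabolite inherits their signal with
flipped sign — including metabolites that are pure noise. On synthetic
data with planted structure this is dramatic: with the metabolome
CLR-transformed, the pure-noise metabolites become "predictable" from
the microbiome and are called well-predicted wholesale, while with the
metabolome left on its intensity scale the noise metabolites are (as
they should be) never called. The package therefore exposes
`metabolome_transform = c("clr", "none")`; all synthetic-data
experiments in the tests and the acceptance script use `"none"`, and
`"clr"` remains the default for real data, where no single metabolite
block dominates the total and the transform's variance-stabilising
benefits apply.

## Cross-validation and the well-predicted call

Evaluation is iterated k-fold cross-validation (defaults k = 10,
10 iterations): within each fold, the 90% training portion is split
80/20 into fitting and early-stopping sets; held-out predictions are
pooled within an iteration before computing per-metabolite Spearman
correlations, and correlations are averaged over iterations (constant
predictions give NA and are excluded from means, with a count
reported). Hyperparameters are tuned once, on the first training
partition, by random search (20 configurations, nested 5-fold CV);
`tune_mode = "every_partition"` re-tunes per fold for those willing to
pay the cost.

The well-predicted cutoff is the 95th percentile of a null SCC pool
from cross-validation runs on sample-shuffled data (pairing destroyed;
re-shuffled each iteration by default, which is the stronger null). All
percentiles in the package use linear interpolation between order
statistics (R's default quantile type 7) — continuous in the pool
values and the common convention. A metabolite is called well-predicted
only when its mean SCC is *strictly* above the cutoff.

A calibration subtlety: the real statistic is a mean over CV
iterations, while the background pool holds per-iteration draws. Under
a true null the mean of m correlated draws has smaller spread than a
single draw, so with many iterations the procedure is conservative
(fewer than 5% of null metabolites are called). The calibration
experiment in the acceptance script therefore computes the real
statistic from a single CV iteration, making it exchangeable with the
pool; with three iterations averaged, the measured null call rate drops
roughly tenfold. For discovery this conservatism is a feature, not a
bug, but it should be kept in mind when comparing call rates across
configurations with different iteration counts.

## Attribution scores and their null

Microbe-to-metabolite attributions use Olden's connection-weight
method: $S = \prod_l W_l$, ignoring biases and activations, with
columns restricted to well-predicted metabolites. For a linear-
activation network this *is* the input–output Jacobian (the tests
verify agreement with central finite differences to $10^{-6}$); with
ReLU layers it is a heuristic summary of signed influence, not a
gradient, and is documented as such.

Significance is judged against the attribution scores of the shuffled-
background models: their mean matrix is flattened and a 97.5th
percentile taken. The literal convention takes the percentile of the
*signed* values; since the test applied afterwards is two-sided
($|\bar S_{ij}|$ above the threshold), the package also offers
`attribution_absolute = TRUE`, the percentile of absolute values. The
signed convention has a failure mode at modest background-model counts:
the mean null matrix concentrates near zero, its upper percentile can
be arbitrarily small or negative, and a non-positive threshold makes
normalization meaningless (the package refuses it with an informative
error). The synthetic experiments use the absolute variant for this
reason; the signed form remains the default surface.

Microbes with no entry of $|\bar S|$ above the threshold are dropped
from all matrices; every matrix is then divided by the threshold and
clipped to $[-1, 1]$ — every significant score is treated with equal
magnitude — and $\bar S$ recomputed from the normalized matrices.

## Consensus module discovery

For each candidate module count k (scanned over 2–20), each per-model
normalized attribution matrix is clustered (rows for microbes, columns
for metabolites) with Euclidean complete-linkage clustering; one
dendrogram per matrix is cut at every k. The consensus matrix M(k)
averages co-membership across models, and its CDF area is

$$A(k) = \sum_j (x_j - x_{j-1})\,\varphi(x_j), \qquad
x_j \in \{0.01, \dots, 1.00\},\; x_0 = 0,$$

with $\varphi(x_j)$ the proportion of entries of M(k) strictly below
$x_j$ (diagonal included; both choices configurable). Setting
$x_0 = 0$ makes the grid widths sum to one so that $A \in [0, 1]$, with
the closed forms the tests pin down: an all-ones consensus has area 0,
a binary consensus has area equal to its zero fraction, a constant-0.5
consensus has area 0.5. The selected count $k^\*$ is the largest k
whose proportional gain $\Delta_k = (A(k) - A(k-1))/A(k-1)$ strictly
exceeds 0.025; $\Delta$ is undefined at k = 2 (no A(1)) so the scan
starts at k = 3 with fallback $k^\* = 2$, and a zero denominator counts
as not exceeding.

**A known behaviour of the Δk rule.** On matrices with a few crisp
planted blocks one might expect $k^\*$ to equal the planted count. It
does not: past the true k, complete linkage must split tight noise
clusters, and those splits vary across replicate matrices, turning
binary consensus entries into fractional ones — which *increases* the
CDF area, typically by more than 2.5% per step, until k reaches 8 or
so. The effect is scale-invariant in the noise level (clustering
geometry is unchanged by rescaling the within-block noise), so no
"cleaner" simulation avoids it; on planted 3×2 block matrices the rule
reproducibly selects around (8, 8). Biclustering at the *true* counts
recovers the planted blocks exactly (adjusted Rand index 1 at zero
noise), so the limitation lies in the count-selection rule, not the
clustering. Users with prior knowledge of the module count should pass
it directly to `bicluster_mean()`.

Module identifiers follow dendrogram leaf order and are arbitrary
labels; all outputs list explicit membership. The module network
averages $\bar S$ over each (microbe module, metabolite module) block,
keeping the sign; the full edge list is always written, and a display
list drops edges with $|score| < 0.25$.

The final model is chosen among candidates trained on the full data by
a match score: candidate modules are greedily paired with reference
modules by maximum member overlap without reuse (an intentionally
transparent rule; optimal bipartite matching would rarely differ on
well-separated modules), the combined microbe + metabolite overlap is
summed with equal weight, and ties break toward the lower candidate
index.

## The synthetic-data generator

`simulate_paired()` emulates the statistical structure the workflow is
built to detect: log-normal compositional microbial abundances with
within-module correlation (a per-sample latent factor per microbe
module), metabolite blocks driven by exactly one microbe module each
through a signed effect — linear, or softplus for a monotone
nonlinearity — plus Gaussian noise, and pure-noise metabolites. The
driver signal is the module's mean log-proportion abundance, centered
per dataset so the softplus operates around zero rather than in its
saturated tail. Metabolite columns are shifted to nonnegative
intensities (rank-based evaluation is unaffected). Defaults (100
samples, 3 microbe modules of 10, 3 driven blocks of 15, 20 noise
metabolites, effect size 2, noise sd 0.5) describe a mid-sized cohort
with clearly detectable but not trivial structure.

What the generator does *not* emulate: mass-spectrometry missingness
and batch effects, zero-inflation of taxa, longitudinal correlation
between samples, and metabolites driven by several microbe modules at
once. Passing tests on this generator therefore demonstrates the
machinery — calibration of the null, recovery of planted signal and
signs, consensus behaviour — not performance on any real cohort.

## Problem sizes and determinism

The test suite and the acceptance script run the full workflow at
reduced cross-validation dimensions (typically 3 iterations of 5-fold
CV and 15 background models, networks of 32–128 units, at most 600
epochs), sizes at which every experiment completes in seconds to a few
minutes on a single core while leaving the statistical conclusions
intact; the vignette-level defaults (10×10 CV, 100 background models)
remain the recommended protocol for real data. Every source of
randomness — partitions, validation splits, initialization, dropout
masks, shuffles, candidate training — derives its seed deterministically
from one master seed, so a rerun with the same configuration reproduces
byte-identical outputs, which the tests verify end to end.
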