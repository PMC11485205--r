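---
title: "Detecting age-related changes in gene-expression coordination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-related changes in gene-expression coordination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordshift)
```

## The model

`coordshift` asks whether the *coordination* between a gene and its
regulatory neighbourhood changes with age, independently of changes in the
gene's own expression level. The analysis rests on a sparse linear
regulatory model: for each target gene $t$ with regulatory neighbours
$N(t)$ and weights $w_{pt}$,

$$\hat y_t \;=\; \sum_{p \in N(t)} w_{pt}\,(x_p - \bar x_p),$$

i.e. the target's expression pattern is reconstructed as a weighted sum of
the *centered* expression of its neighbours. The model is trained once, on
reference data without age structure, and then frozen: it is treated as
external knowledge about who regulates whom and how strongly, and is never
re-fit on the study data. Centering is computed on the evaluation sample
set (e.g. within a tissue), so reconstruction is always relative to the
local mean and adding a constant to any predictor changes nothing.

*Predictability* of gene $t$ in a set of samples is the Spearman
correlation between its observed and reconstructed patterns. Because it is
rank-based, predictability is invariant to monotone transforms and to the
overall expression scale; it responds only to whether the gene still moves
*with* its neighbourhood. Computed within each of six age groups and
regressed on the group-average age, its slope is the quantity of interest:
a negative slope means the gene's coordination with its regulatory
neighbourhood erodes with age.

Assumptions worth stating explicitly:

* relationships are linear in log-space — nonlinear couplings and
  interactions are outside the model class by design;
* the regulatory model transfers from the training context to the study
  context (the calibration and filtering steps below exist to limit the
  damage when it does not);
* predictability is estimated per age group from a few dozen samples, so
  individual Spearman values are noisy; the analysis therefore works with
  slopes over groups and calibrates them with permutation and network
  nulls rather than trusting single values.

## Training the regulatory model

`train_network()` combines L1-regularised regression with stability
selection. For each target, `n_subsamples` (default 100) random halves of
the samples are drawn (`subsample_fraction` 0.5); a lasso path is fit per
subsample on z-scored data; a candidate's selection frequency is the
fraction of subsamples in which its coefficient is nonzero; candidates
with frequency at or above `selection_threshold` (default 0.6, a standard
stability-selection operating point) become predictors. Final weights are
ordinary least squares of the centered target on the centered selected
predictors, so weights live in expression units and reconstruction is a
plain weighted sum.

Two numerical policies deserve explanation because the method's behaviour
depends on them:

* **Per-subsample regularisation.** The path is evaluated on a fixed
  50-point log grid computed from the full data, and each subsample uses
  the smallest grid value at which at most `max_predictors_per_fit`
  (default 20) coefficients are nonzero. This bounds per-fit complexity
  while letting genuinely informative predictors accumulate frequency.
* **The noise floor of the grid.** The grid never descends below
  $\sqrt{2\log(\max(p,4))/m}$ (on z-scored data, $m$ the subsample size,
  $p$ the candidate count) — the scale of the largest spurious correlation
  among independent candidates. Without this floor, fits with few
  candidates would reach the near-OLS end of the path and select pure
  noise in every subsample; chance correlations of order $1/\sqrt{n}$
  persist across subsamples, so no amount of resampling would reject them.
  The floor at $p = 4$ keeps single-candidate fits on the same scale.

At transcriptome scale, candidates are optionally pre-filtered to the 500
strongest marginal correlations (`prefilter_above` 1000 genes); this is a
computational measure, configurable and off at desk scale.

## Network post-processing

Trained edges pass through three cleaning steps, in this order, with these
constants:

* **Reciprocal-edge pruning** (`prune_residual_edges`): for each pair
  $i \to j$, $j \to i$, the ratio $\min(|w_{ij}|,|w_{ji}|) /
  (|w_{ij}|+|w_{ji}|)$ is computed; below 0.1 the weaker edge is removed.
  A strongly asymmetric reciprocal pair usually reflects one real
  direction plus a residual artefact.
* **Same-arm removal** (`remove_same_arm_predictors`): predictors on the
  target's own chromosome arm are dropped when annotation is available,
  because shared local effects (e.g. copy-number changes in the training
  data) masquerade as regulation.
* **Largest weakly connected component**
  (`largest_connected_component`), with a lexicographic tie-break so the
  operation is deterministic.

## Calibration against nulls

Two nulls guard the analysis:

* **Target-swap randomization** (`randomize_targets`) rewires the model by
  exchanging the targets of random edge pairs — weights stay with their
  predictor slot, both degree sequences and the weight multiset are
  preserved, and self-edges/duplicates are skipped and re-drawn. One full
  pass attempts exactly one swap per edge. Reconstructing with the
  randomized model and taking the 95th percentile (linear interpolation
  between order statistics) of the resulting per-gene Spearman
  distribution yields the *inclusion threshold*: genes whose mean
  predictability under the true model does not exceed what a topologically
  equivalent but biologically meaningless model achieves are excluded.
* **Age permutation** (`permutation_null`): the six group ages are
  permuted (100 times by default, with replacement over permutations) and
  all slopes refit. The real p-value distribution is compared against the
  permutation average; per-gene p-values are deliberately *not*
  multiplicity-corrected — the permutation ensemble is the calibration
  instrument.

Hits are the `n_top` (default 100) genes with the smallest slope
p-values (ties by larger absolute slope, then gene id), optionally
restricted to genes whose slope keeps its sign when the oldest group —
the smallest and noisiest in the motivating data — is excluded.

## Driver attribution and module decomposition

For each hit, `classify_hits()` asks whether the predictability change is
accompanied by a change in expression level (per-sample OLS slope of
expression on age, in log2 units/year) or in expression variance
(within-group $n-1$ variances regressed on group ages). A change requires
the absolute slope to reach `cutoff` (default 0.001 per year) *and* sign
consistency with/without the oldest group. Expression slopes use plain
per-gene OLS rather than empirical-Bayes moderation: moderation shrinks
variances, not point estimates, and every downstream rule here operates on
the point estimate.

`within_between_contributions()` decomposes a hit's change into
within-module versus between-module neighbour contributions: for each
(hit, neighbour) pair, the within-group Pearson correlation is regressed
on age, and slopes are accumulated as $\sum_{pairs} w \cdot
\mathrm{slope}$ per (direction, scope) cell, "within" meaning the pair
shares at least one gene set. **Signed weights are the default**, and this
is a deliberate deviation from the obvious $|w|$ choice: for a negatively
coupled neighbour the baseline correlation is negative, so decoupling
*raises* the correlation toward zero; $w \cdot \mathrm{slope}$ maps every
loss of coordination to a negative contribution regardless of coupling
sign, whereas $|w| \cdot \mathrm{slope}$ lets positive- and
negative-weight neighbours cancel. We observed exactly this cancellation
on planted between-module decoupling before flipping the default
(`signed_weights = FALSE` restores the magnitude variant). The weighted
average divides by $\sum |w|$ in both variants. Subnetworks for inspection
are built from the 20 strongest hits by absolute slope plus their
immediate neighbours.

Smoothing of per-gene slopes over the network (`propagate_scores`) uses
the symmetrized model (reciprocal weights summed), row-normalised on
absolute weights — negative entries would otherwise produce signless
mixing — and the fixed-point iteration
$F \leftarrow \alpha A F + (1-\alpha) F_0$ with $\alpha = 0.2$, which
converges geometrically for $\alpha < 1$ and equals
$(1-\alpha)(I-\alpha A)^{-1}F_0$.

## The synthetic generator and what it does (not) show

`simulate_network()` / `simulate_expression()` generate studies with a
known answer: a modular DAG in a random topological order (the model is a
set of per-target linear equations, not a dynamical system, so a single
forward pass suffices), weights drawn from $\pm U[0.3, 1.5]$ and rescaled
per target so each predictor sum has a fixed signal sd, six decade age
groups (ages 25–75) of 40 samples, and planted effects: per-gene coupling
multipliers over age groups (whole-sum or restricted to within-/
between-module edges), per-year mean drift, and per-year multiplicative
noise-scale drift.

**Scale choices are benchmark design, fixed a priori.** Correlations are
scale-free but the driver cutoffs (0.001/year) are absolute, so the scale
determines what "no change" looks like. With signal sd 0.12 and noise sd
0.03 (log2 units), the null expression-slope standard error at 6x40
samples is about 0.0005/year — comfortably below the cutoff — while the
planted variance drift (noise-scale drift 0.18/year on top of coupling
rising 0.1 to 2) produces variance slopes near 0.003/year, clearly above
it. Planted effects live on leaf targets (out-degree zero) so no planted
gene feeds another and recovery is not confounded by cascading secondary
trends.

One emergent property deserves honesty: a gene's expression-slope noise is
almost entirely *inherited*. A non-root gene is a weighted sum of its
parents plus small private noise, so a chance age-aligned drift in a root
gene's finite-sample draws propagates to its whole descendant cone. The
per-simulation false-positive rate of the expression-change flag is
therefore not a stable small number but bimodal across seeds — near zero
when no root drifts, and a sizeable fraction of the interior when one
does. Real data share this structure (latent upstream factors drifting
with age), which is worth remembering when interpreting the
expression-change counts on any single dataset.

What the generator does not emulate: tissue composition, ischemic-time
artefacts, single-cell dropout, or count overdispersion beyond Poisson
(the count export is `Poisson(size factor x baseline x 2^x)`). Passing
tests therefore demonstrate correctness of the machinery and calibration
under the stated generative model, not robustness to those artefacts.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the package's own
benchmark conditions: null calibration and recovery on 500 genes x 6
groups x 40 samples; the decomposition on 20 replicate 120-gene studies;
training accuracy on 120 genes x ~200 samples with 30 subsamples;
propagation checked against the closed form to 1e-8; all brute-force
oracle comparisons to 1e-10 or exact. Degenerate inputs follow fixed
rules: constant genes get slope 0 and p 1; zero-variance vectors yield
missing correlations; collinear OLS falls back to ridge with penalty 1e-8
and a warning; isolated nodes keep their own score under propagation;
quantiles interpolate linearly between order statistics; all randomness
flows from explicit seeds, with per-stage seeds derived by hashing the
stage name.

## Known limitations

* Linearity: age-related changes in nonlinear relationships are invisible.
* Per-group Spearman values at n = 40 carry substantial noise; six groups
  give four residual degrees of freedom per gene, so single-gene p-values
  are weak evidence and only the calibrated ensemble behaviour is
  interpretable.
* The inclusion threshold from a single target-swap randomization is
  itself an estimate; `n_randomizations` can be raised.
* The generator's Gaussian, Poisson-export world is cleaner than RNA-seq;
  preprocessing is validated against oracles, not against real library
  artefacts.
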