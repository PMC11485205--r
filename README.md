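# coordshift

Aging changes not only *how much* genes are expressed, but how well their
expression stays **coordinated** with the rest of the regulatory network.
`coordshift` detects such age-related gains and losses of gene–gene
coordination in bulk expression studies. It is aimed at computational
biologists who have (a) a gene-by-sample expression matrix with per-sample
age groups and (b) either reference data to train a regulatory model on, or
an existing weighted gene–gene model.

## The method in brief

A sparse linear regulatory model — trained by L1-regularised regression
with stability selection on reference data, or supplied as a weighted edge
list — gives, for every target gene *t*, neighbours *N(t)* and weights
*w<sub>pt</sub>*. The target's expression is reconstructed as

&nbsp;&nbsp;&nbsp;&nbsp;ŷ<sub>t</sub> = Σ<sub>p∈N(t)</sub> w<sub>pt</sub> (x<sub>p</sub> − x̄<sub>p</sub>),

and its **predictability** is the Spearman correlation ρ(y<sub>t</sub>,
ŷ<sub>t</sub>), computed within each age group. Per gene, predictability is
regressed on the group-average age (Predictability ~ Age, two-sided t-test
on the slope); the analysis is calibrated by a degree-preserving
target-swap network null (95th-percentile inclusion threshold), an
age-permutation null (100 permutations), and a slope-sign consistency check
excluding the oldest group. The top-100 hits are then attributed to drivers
(expression-level slope and within-group variance slope, |slope| ≥ 0.001
per year) and decomposed into within-module versus between-module
correlation changes weighted by the model coefficients. All method
constants (prune ratio 0.1, quantile 0.95, 100 permutations, cutoff 0.001,
top-100 hits, 20-strongest subnetworks, propagation α = 0.2, minimum mean
count 100, poor-prediction threshold 0.2) are defaults of
`validate_config()`.

A first-class synthetic-data module generates studies with a known modular
regulatory network and planted coordination changes, so every stage is
testable without external data.

## Worked example

Simulate a 500-gene study (6 age groups × 40 samples) in which 50 genes
lose coordination with age (coupling declining 1 → 0.2) and 10 genes gain
coupling while their noise variance grows, then run the predictability
analysis with the true network as the frozen model:

```r
library(coordshift)

b  <- simulate_benchmark("recovery", seed = 1)
an <- analyze_benchmark(b, n_top = 100)
head(an$hits[, c("gene", "slope", "p_value", "direction", "rank")], 5)
#>    gene         slope      p_value direction rank
#> 1 g0201  0.0004518896 0.0000893029  increase    1
#> 2 g0368 -0.0013755025 0.0042674084  decrease    2
#> 3 g0310  0.0006550523 0.0043761329  increase    3
#> 4 g0124 -0.0111031895 0.0061800020  decrease    4
#> 5 g0003 -0.0095883141 0.0071982591  decrease    5

mean(b$planted$loss %in% an$hits$gene)   # recall of planted losses
#> [1] 0.98
```

Each hit row is a gene whose predictability changes with age: `slope` is
the change in Spearman correlation per year (e.g. −0.011/year for `g0124`
≈ −0.55 over the 50-year range), `p_value` the two-sided t-test on that
slope, and `direction` whether coordination is gained or lost. 49 of the
50 planted coordination-loss genes are recovered among the top-100 hits.

The same workflow runs end-to-end from a YAML configuration, on simulated
or supplied data:

```r
res <- run_pipeline(validate_config(list(
  seed = 5, out_dir = "out",
  simulate = list(enabled = TRUE, n_genes = 200))))
```

which writes the model, per-gene trends, hits, driver classification,
within/between contributions, subnetworks, a ranked `.rnk` export for
preranked enrichment tools, and a hashed run manifest. A thin CLI wrapper
(`inst/cli/coordshift`) exposes `run` and `simulate` subcommands.

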