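---
title: "Dual-network analysis of paired treatment studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-network analysis of paired treatment studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualnets)
```

# The analysis problem

`dualnets` implements a weight-of-evidence workflow for paired pre/post
treatment expression studies, of the kind used to characterize drug action on
a tissue (the motivating design is an airway-epithelium study of an inhaled
glucocorticoid in asthmatics: two arms, one pre- and one post-treatment array
per subject). A single differential-expression analysis of such a study is
statistically fragile — a handful of genes survive multiple-testing
correction — so the workflow mines the same data through two independent
network lenses and then asks which biological pathways both lenses agree on:

1. **Co-expression branch.** Baseline-corrected profiles are turned into a
   mutual-information (MI) co-expression network; densely interconnected
   modules are extracted with an MCODE-style algorithm.
2. **Interactome branch.** Per-gene differential-expression P-values are
   mapped onto a protein-protein interaction network, converted to node
   scores through a beta-uniform mixture (BUM) model, and the maximum-weight
   connected subgraph is extracted.
3. **Common pathways.** Each module's gene list is tested for pathway
   over-representation; pathways significant in modules from *both* branches
   are the workflow's product, and each one receives an empirical
   permutation P-value for the chance of co-occurring in size-matched random
   gene lists.

# Preprocessing model

Expression input is a log2 matrix (genes x arrays) with per-sample
annotations. Two operations precede all statistics:

* **Background filtering by a sex marker.** A gene expressed in one sex
  only (XIST being the canonical example) provides an internal estimate of
  the array background: its median intensity in the non-expressing sex. A
  gene is kept when *any* array reaches that threshold; ties count as
  expressed. The filter is idempotent and the marker itself is not
  special-cased.
* **Baseline correction.** Each subject's pair of arrays collapses to a
  post-minus-pre log2 difference, removing inter-individual offsets.
  Subjects lacking a complete pair are dropped with a warning, not imputed —
  the same decision a study makes when an array fails quality control.

# Differential expression

Per-gene ordinary least squares on the baseline-corrected values with
treatment (0/1), sex (0/1) and standardized age in the design; the quantity
of interest is the treatment coefficient (the treated-minus-placebo
difference in mean change). Variances are moderated with the standard
empirical-Bayes approach: the prior degrees of freedom `d0` and prior
variance `s0²` are estimated by moment matching on the log residual
variances (digamma/trigamma inversion), each gene's variance is shrunk to
`(d0·s0² + dg·sg²)/(d0 + dg)`, and two-sided P-values come from a t
distribution on `d0 + dg` degrees of freedom. When the trigamma inversion
has no positive solution (essentially homogeneous variances) `d0` is capped
at 10^6 with a warning — numerically the `d0 → ∞` limit. The test suite
verifies the implementation against the reference empirical-Bayes
implementation in `limma` to 10^-6. Benjamini–Hochberg q-values are appended
via `stats::p.adjust`; the suite checks it against a literal step-up
implementation.

# Mutual-information network inference

## Estimator

Profiles are first copula-transformed (`rank/(n+1)`), making the MI
estimate invariant to monotone transforms. Densities on the unit square are
estimated with Gaussian kernels of width `h`, with boundary reflection at 0
and 1. The naive resubstitution estimate

\[ \hat I_h = \frac1n \sum_i \ln\frac{\hat f_2(x_i, y_i)}{\hat f_1(x_i)\hat f_1(y_i)} \]

carries two leading biases: a *positive* `a/(n h²)` term from each point's
own kernel mass, and a *negative* `b·h²` smoothing term that flattens
concentrated dependence. Neither can be made simultaneously small at a
single width: empirically, widths small enough to be accurate for strong
dependence inflate the independence baseline and vice versa. `dualnets`
therefore evaluates the raw estimate at the three widths `(0.6, 1, 1.4)·h`
and solves the three-parameter model `I + a/h_i² − b·h_i²` exactly, taking
the bias-free intercept (clipped at zero). Against the bivariate-Gaussian
closed form `−½ ln(1−ρ²)` at `n = 1000`, `h = 0.04`, mean errors across
seeds are within ±0.02 nats at ρ ∈ {0, 0.5, 0.9}.

## Calibration

* `calibrate_kernel_width()` grid-searches `h` by simulating bivariate
  Gaussians at the study's sample size and minimizing total squared error
  against the closed form. Accuracy-optimal widths shrink with `n`
  (≈0.04 at n = 1000, ≈0.1–0.15 at n = 30).
* `calibrate_mi_threshold()` simulates independent profile pairs at the
  study's sample size and fits `ln P(MI > I₀) = α + β·I₀` over the *top 20%*
  of the null only. Restricting to the tail matters: the null bulk decays
  more slowly than exponentially, and including it flattens `β`, inflating
  every downstream threshold severalfold. `threshold_for_p()` inverts the
  line at the chosen tail probability.

## Operating parameters

The `build_network()` threshold `I₀` derives from a null tail probability.
The pipeline default is `1e-3` *in combination with the bootstrap
consensus*: a mild cutoff admits a handful of false edges per network
(~10³ candidate pairs x 10^-3), but false edges do not recur across
subject resamples and the consensus filter removes them, whereas a strict
cutoff makes the network acutely sensitive to the sampling variance of the
extrapolated threshold — an unlucky null fit can thin a genuine module
below detectability. Used without consensus, choose stricter cutoffs;
genome-scale studies testing ~10⁸ pairs operate down at 10^-8. The pipeline's
default width is 0.22 — the established operating scale for ~30-subject
paired studies — rather than the accuracy-optimal width, because
thresholding rewards a smoother, lower-variance null; pass
`kernel_width = NULL` to recalibrate.

**DPI.** `apply_dpi()` removes, in every triangle, the weakest edge when it
is at most `(1 − tolerance)` times the smaller of the other two — the
data-processing-inequality interpretation of the weakest edge as an
indirect dependence. All triangles are examined on the original weights and
removals applied at once, making the operation idempotent. `build_network()`
applies DPI by default, but `run_pipeline()` disables it: a latent-factor
co-expression module is a near-clique in which almost every edge is
"indirect" through the factor, so DPI reduces the module to a tree and
dense-module detection finds nothing. DPI is the right default when the
goal is regulatory topology; it is the wrong default upstream of MCODE.

**Bootstrap consensus.** `bootstrap_consensus()` rebuilds the thresholded
network on `B` resamples of subjects (default 100) and keeps edges whose
support count is improbable under `Binomial(B, p̂)`, `p̂` being the mean
bootstrap edge density, with Bonferroni correction over all candidate edges
and retention at corrected `q < 0.001`. The binomial null is the package's
concrete reading of "consensus": an edge must recur far more often than the
network's overall density predicts.

**Degree diagnostics.** `fit_power_law()` offers log-binned log-log
regression and a discrete MLE with a Hurwitz-zeta normalizer (direct
summation plus Euler–Maclaurin tail). Parameter recovery for γ = 2 on 10⁴
draws is within ±0.1 for the MLE; the regression variant is kept for
comparability with degree-distribution plots but is a visibly cruder
estimator.

# MCODE-style module detection

Vertex weight = `k_max` x density of the highest k-core of the closed
neighborhood. Complexes grow from the highest-weight unvisited seed,
admitting neighbors whose weight is at least `seed_weight·(1 − vwp)`
(default `vwp = 0.2`, the plugin default, with degree cutoff 2, haircut on,
fluff off). The haircut is implemented as the 2-core of the complex, and
complexes that contain no 2-core are discarded. Fluff (off by default)
follows the original ordering — fluff before haircut — and is the one
setting under which complexes may overlap. Scores are density x size; all
ties (seed selection and ranking) break by lexicographically smallest
vertex id, which makes the output independent of input vertex order — a
property the suite tests by permutation.

# Interactome scoring and module search

The P-value density is modeled as `f(p) = λ + (1−λ)·a·p^(a−1)` — a uniform
noise floor plus a Beta(a, 1) signal spike at zero — and fitted by
multi-start bounded maximum likelihood (λ constrained to [0.01, 0.99] to
avoid the pure-uniform ridge). From the fit, the P-value threshold
attaining a target FDR is closed-form, and node scores
`(a − 1)(ln p − ln τ)` are positive exactly below τ.

Two searches for the maximum-weight connected subgraph are provided:

* `find_module_exact()` — branch-and-bound over connected vertex subsets
  with an admissible bound (current score plus all still-admissible positive
  scores), enforced at ≤30 vertices. It equals exhaustive enumeration on
  every random 12-vertex instance in the suite.
* `find_module_heuristic()` — positive components become super-nodes; the
  cheapest connecting paths (penalty = scores of crossed negative vertices)
  define a metric closure whose minimum spanning tree is pruned of leaves
  that cost more than they contribute. The result is connected, never
  scores below the best single positive component, never exceeds the exact
  optimum, and matches it on ≥90% of random 12-vertex instances.

A practical note on recovery expectations: with 15 planted signal nodes at
`Beta(0.1, 1)` P-values and FDR 0.05, the fitted τ is ≈2x10^-3 and only
~55% of signal nodes score positive. Recovery of the planted set is
therefore intrinsically partial — exact search on candidate subgraphs does
no better than the heuristic here — and per-instance Jaccard overlap with
truth is bimodal. The suite and acceptance script report the median over
ten seeded replicates.

# Enrichment and common pathways

Over-representation uses the exact hypergeometric upper tail
(`stats::phyper`; the suite checks the entire `N ≤ 25` grid against direct
binomial-coefficient summation). The conditional ontology test processes
terms children-before-parents, removing genes annotated to
already-significant descendants from both the term's annotation set and the
query overlap — so a parent is only called on evidence not explained below
it. Conditioning uses the same α as reporting (0.05) unless overridden; for
multi-parent terms, all significant descendants condition regardless of
path.

Reporting filters mirror common practice: disease-category pathways are
dropped (with an exception list for disease terms that are themselves the
study phenotype), pathways supported by fewer than two genes in the module
where they were called are dropped, and modules left with no annotated
genes in surviving pathways are discarded. Term clustering for heatmap
display uses 1 − Pearson distance with average linkage (the linkage is a
package choice, recorded in the output).

`permutation_p()` draws, per iteration, two *independent* random gene lists
of the observed module sizes (independence is the most direct reading of
"random lists of the same size"; coupling is not modeled), repeats the
identical enrichment-filter-intersect analysis, and reports `p = n/N` per
target term. Zero counts are reported as 0 with the resolution floor `1/N`
noted, alongside a `(n+1)/(N+1)` corrected estimate. On a fixture whose
co-enrichment probability is analytically computable, the empirical rate
sits inside the binomial 99% band at `N = 1000`.

# The synthetic study

`generate_study()` emulates the motivating design: 30 subjects (two arms,
paired arrays), sex and age covariates, one sex-marker gene
(female ~ N(10, 1), male ~ N(5, 0.5) on the log2 scale, mimicking the
bimodal XIST distribution), latent-factor co-expression modules — gene `g`
in module `m` has post-minus-pre difference
`√r·f_{m,s} + √(1−r)·ε` so the within-module correlation is exactly `r` in
expectation — and treatment-responsive genes shifted by `effect_size` in
the treated arm only. `generate_planted_network()` grows a
preferential-attachment graph at `m = 3` edges per node (matching the
~6–7 mean degree of curated human interactomes), plants a connected signal
subgraph by seeded breadth-first growth, and draws signal P-values from
`Beta(a, 1)` against a uniform background — the exact generative model the
BUM fit assumes. Defaults (30 subjects, module correlation 0.8, effect
size 1 log2 unit, 15 signal nodes on 200, `a = 0.1`) are the package's
standing study conditions.

What the generators deliberately do *not* model: probe-level effects, batch
effects, missing values, correlated covariates, hub-biased signal
placement, and annotation incompleteness. Passing tests on these fixtures
demonstrate that the algorithms recover the structures they are designed
for under the stated noise model — not that any real dataset will behave as
cleanly.

# Numerical choices and degenerate inputs

* MI is clipped at zero; an all-tied profile copula-transforms to 0.5
  everywhere with a warning.
* The MI null fit refuses degenerate (constant) nulls; `threshold_for_p`
  requires `p ∈ (0, 1]`.
* BUM fitting clamps zero P-values to the smallest positive double with a
  warning and refuses constant inputs.
* All-zero residual variances fall back to ordinary t with a warning;
  zero-variance genes get P = 0 or 1 by the sign of the coefficient.
* Exhaustive-search ties break by smaller module, then lexicographic ids;
  all tabular outputs sort by P-value then identifier.
* Problem sizes in the tests — 30 subjects, 80–120 genes for network
  recovery, 200-node interactomes, 1000 permutations — are the package's
  chosen demonstration scale: large enough for every statistical property
  under test to be measurable, small enough to iterate on.

# Known limitations

* The exact subgraph solver is deliberately capped at 30 vertices; the
  heuristic is the production path, and it is a heuristic.
* The MI threshold calibration fits one sample size at a time; no pooled
  `n·I₀` scaling law is assumed, because the tail slope's dependence on `n`
  is left empirical.
* The permutation null matches list sizes but not annotation bias (random
  lists are drawn uniformly from the universe).
* The BUM model assumes a monotone signal density at zero; P-value
  distributions with interior modes will fit poorly.
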