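# dualnets

Dual-network module analysis for paired pre/post treatment expression
studies.

## The problem

In a paired two-arm design (each subject profiled before and after
treatment with drug or placebo), single-gene differential-expression
analysis is often underpowered: after multiple-testing correction only a
handful of genes survive, and the biology of the treatment response stays
out of reach. `dualnets` implements a weight-of-evidence workflow that
mines the same study through two independent network representations and
reports the pathways both agree on:

1. **Co-expression branch** — baseline-corrected profiles (per-subject
   post − pre log2 differences) are turned into a mutual-information
   network; densely interconnected gene modules are extracted with an
   MCODE-style algorithm.
2. **Interactome branch** — per-gene P-values are mapped onto a
   protein-protein interaction network, converted into node scores via a
   beta-uniform mixture (BUM), and the maximum-weight connected subgraph is
   extracted (exact branch-and-bound at small scale, a Steiner-tree-style
   heuristic beyond).
3. **Common pathways** — modules from both branches are tested for pathway
   over-representation; pathways significant in both receive an empirical
   permutation P-value (`P = n/N` over N size-matched random gene lists).

## Core statistics

* Gaussian-kernel mutual information on copula-transformed profiles, in
  nats (for bivariate Gaussians, MI = −½ ln(1 − ρ²)); kernel width and MI
  threshold calibrated by simulation at the study's sample size; optional
  data-processing-inequality pruning and bootstrap-consensus edges.
* Empirical-Bayes moderated t per gene:
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), with the prior (d₀, s₀²) estimated
  by digamma/trigamma moment matching; Benjamini–Hochberg q-values.
* MCODE vertex weight = k_max × density of the highest k-core of the closed
  neighborhood; complexes scored density × size.
* BUM P-value density f(p) = λ + (1 − λ)a·p^(a−1); FDR-calibrated node
  scores s(p) = (a − 1)(ln p − ln τ).
* Hypergeometric over-representation with ontology-conditional testing and
  a size-matched permutation null for cross-network pathway overlap.

A seeded synthetic-data module generates the whole study design — paired
arms, sex/age covariates, a sex-marker gene for background estimation,
latent-factor co-expression modules, treatment-responsive genes, and a
scale-free interaction network with a planted high-signal subnetwork — so
every stage is testable end to end without external downloads.

## Worked example

```r
library(dualnets)
cfg <- pipeline_config(seed = 1, bootstrap_cycles = 50, permutation_N = 200)
report <- run_pipeline(cfg)
print(report)
```

```
dual-network pipeline report
  genes after background filter: 120 | subjects: 30
  DE genes: P<alpha: 15 | q<alpha: 10
  co-expression network: 120 nodes, 447 edges (I0 = 0.18 nats)
  degree power-law gamma: 1.38
  MCODE complexes: 1 | M1 size: 30
  interaction module: 6 nodes
  common pathways: shared_signaling
```

Reading the output: 120 simulated genes pass the sex-marker background
filter; 15 genes reach P < 0.05 (10 at q < 0.05) for the treatment
contrast; the bootstrap-consensus MI network at threshold I₀ = 0.18 nats
contains one dense complex — exactly the 30-gene planted co-expression
module (`report$mcode_m1_genes`) — while the BUM-scored interactome search
returns a 6-node module inside the planted signal subnetwork. One gene set
("shared_signaling", constructed to straddle both planted structures) is
significantly enriched in both modules, and its permutation P-value
(`report$permutation`) is 0/200: it never arose as a common pathway in
size-matched random lists.

Individual stages are exported and composable: `generate_study()`,
`filter_unexpressed()`, `baseline_correct()`, `fit_linear_model()`,
`moderate_and_test()`, `build_network()`, `bootstrap_consensus()`,
`find_complexes()`, `fit_bum()`, `score_nodes()`, `find_module_exact()`,
`find_module_heuristic()`, `ora()`, `conditional_ora()`,
`filter_pathways()`, `common_terms()`, `permutation_p()`. A thin
command-line wrapper lives at `inst/scripts/run-pipeline.R`.

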