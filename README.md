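# mxassort

Strength-assortativity analysis of two-layer multiplex brain networks.

Structural connectivity (SC; anatomical links weighted by tractography
streamline counts) and functional connectivity (FC; statistical dependence
between regional activity) describe the same brain but are organized
differently. `mxassort` couples per-subject SC and FC matrices one-to-one
into a multiplex network and asks a single, precise question at every scale:
do connected nodes have similar total connection weight? It is aimed at
network-neuroscience researchers who want the full battery — within-layer,
subnetwork-block, between-layer and per-hemisphere strength assortativity
with cohort-level inference — runnable end-to-end on synthetic cohorts with
known ground truth.

## What it computes

**Node strength assortativity.** With binary adjacency `A_ij`
(`|w_ij| > 1e-12`), degree `k_i`, `2m = Σ k_i` and signed strength
`s_i = Σ_j w_ij`:

    r = Σ_ij (A_ij − k_i k_j / 2m) s_i s_j
        ───────────────────────────────────
        Σ_ij (k_i δ_ij − k_i k_j / 2m) s_i s_j

equivalently the Pearson correlation of endpoint strengths over all `2m`
ordered edge endpoints (a Spearman variant uses midranks over that
multiset). Restricted to edges between two of the seven canonical
resting-state networks it fills a 7×7 block matrix; across layers, the
one-to-one coupling reduces it to the correlation of the two layers'
strength vectors.

**Sparse FC estimation.** FC is estimated from regional time series as
elastic-net regularized partial correlations: each node's z-scored series is
regressed on all others under the penalty
`λ[(1−α)‖β‖²/2 + α‖β‖₁]`, hyperparameters chosen by 10-fold
cross-validation (grid, or expected-improvement search over a
Gaussian-process surrogate of the CV loss), and the directed coefficients
symmetrized as

    ρ̂_ij = sign(β̂_j⁽ⁱ⁾) · min{1, √(β̂_j⁽ⁱ⁾ β̂_i⁽ʲ⁾)}   if signs agree, else 0.

**Inference.** Left-vs-right hemispheric differences are tested per measure
and subnetwork with a paired sign-flip Monte-Carlo permutation test
(10,000 draws, add-one corrected, two-tailed) under Bonferroni correction.

**Synthetic cohorts.** A generator produces SC-like (log-normal positive)
and FC-like (signed sparse) layers, rewires them to target assortativities
by degree-preserving swaps, couples them at a target interlayer strength
correlation by bisection blending, and can inject a known lateralized shift
— so every statistic is validated against ground truth.

## Worked example

```r
library(mxassort)
co  <- generate_cohort(cohort_spec(n_subjects = 10, n_nodes = 60, seed = 1))
rep <- run_full(run_config(mode = "simulate", n_permutations = 2000,
                           seed = 1), cohort = co)
print(rep)
#> <run_report> 10 subjects, 242 undefined cells
#>   within_sc  median +0.0825 (MAD 0.0020, n = 10)
#>   within_fc  median -0.1335 (MAD 0.0047, n = 10)
#>   between    median +0.1065 (MAD 0.0139, n = 10)
#>   hemispheric tests: 0 of 12 significant at adjusted 0.05
```

The cohort was generated with targets +0.10 (within SC), −0.15 (within FC),
+0.10 (between): the report recovers the assortative-SC / disassortative-FC
/ positive-coupling signature, and — with no lateralized effect injected —
no hemispheric test rejects. Cells whose restricted edge set is degenerate
(e.g. small RSN blocks) are reported as undefined, never as zero.

The estimator side, on a 3-node chain A–B–C (true partial correlation 0.5
on each link, none between A and C):

```r
g     <- make_ggm("chain", partial_corr_magnitude = 0.5)
panel <- sample_timeseries(g, 1000, seed = 2)
fc    <- estimate_fc(panel, elastic_net_config(search_method = "grid",
                                               n_search_points = 50, seed = 3))
round(fc$weights, 3)
#>       A     B     C
#> A 0.000 0.480 0.026
#> B 0.480 0.000 0.502
#> C 0.026 0.502 0.000
cor(panel$data[, "A"], panel$data[, "C"])   # 0.353
```

Full correlation invents an A–C link (0.35); the regularized partial
correlation all but removes it (0.026) while recovering the true links near
their 0.5 magnitude.

A thin command-line wrapper lives in `inst/cli/mxassort-pipeline.R`
(subcommands `simulate`, `estimate-fc`, `assort`, `run`).

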