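---
title: "Strength assortativity in two-layer multiplex brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strength assortativity in two-layer multiplex brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxassort)
```

## The scientific question

Structural connectivity (SC) — anatomical links between cortical regions,
weighted by tractography streamline counts — and functional connectivity
(FC) — statistical dependence between regional activity time series — are
correlated but organized differently. `mxassort` treats the two as layers of
a two-layer *multiplex* network: every region (node) exists in both layers
and is coupled one-to-one to its own replica in the other layer. The central
statistic is **node strength assortativity**: do nodes tend to connect to
other nodes of similar total connection weight? Within a layer, positive
values (assortative mixing) are associated in the network-science literature
with robustness to random failure; between layers, positive strength
coupling mitigates cascading failures in interdependent systems. The package
computes this statistic within layers, between resting-state-network (RSN)
blocks, between the coupled layers, and separately per hemisphere, and tests
hemispheric differences by paired permutation.

## The assortativity coefficient

For a layer with binary adjacency $A_{ij}$ (an edge exists when
$|w_{ij}| > 10^{-12}$), degree $k_i$, $2m = \sum_i k_i$, and signed strength
$s_i = \sum_j w_{ij}$, the coefficient is

$$r = \frac{\sum_{ij} (A_{ij} - k_i k_j / 2m)\, s_i s_j}
           {\sum_{ij} (k_i \delta_{ij} - k_i k_j / 2m)\, s_i s_j},$$

the covariance of endpoint strengths over edges divided by their variance.
Equivalently, $r$ is the Pearson correlation of the strengths at the two
ends of an edge, taken over all $2m$ ordered edge endpoints — the test suite
holds the implementation (the matrix double sum above) to that enumeration
oracle at $10^{-10}$. The Spearman variant replaces each strength by its
midrank over the same endpoint multiset (a node of degree $k_i$ appears
$k_i$ times; ties get average ranks), making it invariant under monotone
transforms of the strengths.

Three conventions matter and are deliberate:

* **Strengths are signed.** FC edges carry signed partial correlations, and
  a node whose positive and negative weights balance has strength near
  zero. An absolute-value mode exists (`absolute = TRUE`) for sensitivity
  analysis only.
* **SC weights enter raw.** Log-transforming streamline counts is treated as
  a display device; `sc_log_transform` in `run_config()` applies it on
  request. Assortativity is invariant to positive rescaling, not to the log.
* **Degenerate cells are undefined, never zero.** Fewer than two edges, or
  zero variance of endpoint strengths, yields an explicit `NA` marker with a
  reason; cohort medians skip such subjects and report how many were
  skipped.

Block (RSN-pair) assortativity restricts the sums to edges joining two
blocks. Whether the strengths in those sums should come from the restricted
edge set or the whole network is genuinely open; the default
(`strength_scope = "block"`) recomputes degree and strength from the
restricted edges, which is self-contained and degenerates gracefully, and
`"global"` is available because either reading is defensible.

Between-layer assortativity follows from the coupling structure: each node's
single interlayer link makes the edge-based statistic collapse to the
correlation of the two layers' strength vectors over the coupled nodes (or a
node subset, e.g. one RSN). This coupled-strength-correlation reading is an
interpretation forced by coupling degree 1; it is documented as such.

## Sparse FC by elastic-net partial correlation

Full Pearson correlation mixes direct and indirect dependence (a chain
A–B–C induces a spurious A–C correlation); naive partial correlation can
invert the problem via Berkson's paradox (conditioning on a common effect
induces dependence between its causes). Both failure modes are built into
`make_ggm()` as 3-node ground truths and verified in the tests. The
estimator regresses each node's z-scored series on all others under the
elastic-net penalty
$\lambda[(1-\alpha)\|\beta\|_2^2/2 + \alpha\|\beta\|_1]$ (glmnet's
parameterization; $\alpha = 1$ is the LASSO) and symmetrizes the two
directed coefficients:

$$\hat\rho_{ij} = \mathrm{sign}(\hat\beta_j^{(i)})\,
  \min\{1, \sqrt{\hat\beta_j^{(i)} \hat\beta_i^{(j)}}\}
  \quad\text{if the signs agree, else } 0,$$

which keeps $\hat\rho \in [-1, 1]$, symmetric, and sparse without any
post-hoc thresholding. Coefficients below $10^{-10}$ in magnitude count as
zero.

Hyperparameters are chosen by 10-fold cross-validation (contiguous time
blocks by default — random folds would leak autocorrelated timepoints in
real fMRI; a `"random"` scheme is available). Because the data give no
guidance on search ranges, the penalty is parameterized *relative* to each
regression's analytic maximal penalty (the smallest $\lambda$ with an
all-zero solution), searched on a log scale over $[10^{-4}, 1]$ with
$\alpha \in [0.05, 1]$; one $(\lambda, \alpha)$ pair per subject minimizes
the CV loss averaged over all node regressions (per-node tuning is a flag).
Two search strategies are provided: an exhaustive grid, and an
expected-improvement search that fits a Gaussian-process surrogate
(squared-exponential kernel, fixed length scale 0.3 on the unit-normalized
rectangle, nugget $10^{-8}$) to the evaluated CV losses and repeatedly
evaluates the candidate maximizing expected improvement. The two agree to
within 5% CV loss on test problems while the EI search spends an order of
magnitude fewer evaluations.

## The synthetic cohort generator

No real imaging data enters this package. The generator emulates, per
subject:

* **SC-like layers**: uniform random graphs with heavy-tailed
  (log-normal, meanlog 2, sdlog 1) strictly positive weights, standing in
  for streamline counts;
* **FC-like layers**: sparser signed graphs with weights in $[-1, 1]$ and a
  positive-sign excess (60/40), standing in for sparse partial correlations;
* **target mixing**: each layer is rewired toward its target assortativity
  by greedy degree-preserving double-edge swaps — a swap is accepted only if
  it moves the measured coefficient strictly toward the target — which
  exactly preserves the binary degree sequence and the edge-weight multiset.
  Simulated-annealing acceptance is deliberately out of scope: the greedy
  rule is monotone and testable, and reaches the modest targets used here;
* **between-layer coupling**: FC edge weights are blended toward (or away
  from) a score built from the SC strength profile, with the mixing
  coefficient found by bisection so the measured strength correlation lands
  within 0.02 of its target. Direct joint control of all three targets is
  analytically intractable; the blend is an artifact choice, and achieved
  per-subject values are always reported (`cohort$achieved`) rather than
  assumed;
* **between-subject variability**: multiplicative log-normal weight jitter
  for SC, additive for FC (`noise_sd`, default 0.05), applied after
  rewiring — so achieved within-layer values drift a few hundredths from
  target while their signs are stable.

Default study conditions are 30 subjects, 100 nodes, SC density 0.15, FC
density 0.10, and targets $+0.10$ (within SC), $-0.15$ (within FC), $+0.10$
(between) — an idealization of the qualitative multiplex signature the
statistics are designed to detect: assortative SC, disassortative FC,
positive interlayer coupling, at magnitudes typical of strength
assortativity in cortical networks. Node metadata defaults to first half
left / second half right, with the seven RSN labels in contiguous blocks per
hemisphere; any labelling can be supplied as a `nodes.tsv`.

What the generator does **not** emulate: spatial embedding and distance-
dependent wiring, hub topology beyond what rewiring induces, temporal
autocorrelation (sampled series are i.i.d. multivariate-normal rows), and
any biophysics of BOLD or tractography. Passing tests therefore demonstrate
correctness of the statistics and estimators under known ground truth — not
that real SC/FC will show any particular effect size.

A known lateralized effect can be injected with
`inject_lateralized_shift()`, which rewires only one hemisphere's
intra-hemispheric FC edges toward a lower assortativity, leaving the other
hemisphere, interhemispheric edges, degrees and the weight multiset
untouched — ground truth for validating the hemispheric test.

## Hemispheric inference

For each (measure, RSN) cell the pipeline compares left and right induced
subnetworks across subjects with a paired sign-flip permutation test:
statistic $T = \mathrm{median}(\text{left} - \text{right})$, null generated
by flipping each subject's difference independently with probability 1/2
(conditional Monte Carlo over the $2^n$ sign assignments, default 10,000
draws), two-tailed p with the add-one correction
$p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + B)$ so finite simulation never
returns zero. Bonferroni correction is applied over the family actually run
in one invocation — 24 tests (3 measures × (global + 7 RSNs)) — and the
family definition is recorded in the output.

One calibration subtlety is worth knowing. The median of sign-flipped
differences has atoms: many sign assignments share the same middle order
statistics, so ties at the observed value occur with positive probability
and the test is strictly conservative (measured type-I rate ≈ 0.032 at
nominal 0.05, n = 20). The mean-difference statistic (`statistic = "mean"`)
has an essentially atom-free null and is calibrated on the nominal level;
the median is kept as the default for robustness to outlying subjects, and
its conservatism only costs power, never validity.

## Numerical choices

* Weight/adjacency zero threshold $10^{-12}$; coefficient zero threshold
  $10^{-10}$; symmetry tolerance on input matrices $10^{-9}$.
* Random-sparse precision matrices are made positive definite by diagonal
  loading (add $|\lambda_{\min}| + 0.1$ when needed) — support is preserved,
  realized partial correlations shrink. A 3-node chain with requested
  magnitude above $1/\sqrt{2}$ is handled the same way.
* The collider is constructed from the covariance side (exact zero marginal
  covariance), with the coupling chosen by root-finding so the realized
  conditional dependence matches the requested magnitude.
* CV predictions interpolate on a 20-point log-spaced warm-start path per
  (node, fold); final coefficients come from exact path-end fits at
  `thresh = 1e-10`.
* One master seed spawns per-subject/per-stage seeds through a small LCG
  (modulus $2^{31}-1$), so results are independent of subject processing
  order.

Problem sizes in the shipped tests (cohorts of up to 30 subjects × 100
nodes, GGMs up to 20 nodes × 1000 timepoints, 1000 null replicates × 2000
permutations for calibration) were chosen as the smallest at which the
studied signs and rates are stable across seeds.

## Known limitations

* The greedy rewiring cannot reach extreme targets (|r| near 1) on sparse
  graphs; it then reports the achieved value honestly (`converged = FALSE`).
* Joint targets (two within-layer values plus the interlayer correlation)
  interact: the blending step perturbs FC strengths and hence its
  within-layer value slightly. Achieved values are the source of truth.
* Per-RSN statistics on small blocks rest on few edges; the undefined-value
  machinery keeps such cells out of medians, but their sampling variance is
  necessarily large — matching a caveat any subnetwork-level analysis of
  real parcellations faces.
* The estimator's false-positive control is what cross-validated prediction
  gives (prediction-optimal penalties admit some spurious edges on
  structured problems); stability selection or FDR-controlled variants are
  intentionally out of scope.

## A minimal session

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(n_subjects = 10, n_nodes = 60, seed = 1))
rep <- run_full(run_config(mode = "simulate", n_permutations = 2000,
                           seed = 1), cohort = co)
print(rep)
subset(rep$summaries, rsn == "global" & hemisphere == "both")
```
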