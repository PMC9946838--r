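---
title: "grnflow: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grnflow: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

grnflow infers cell-state-specific gene-regulatory networks (GRNs) from
single-cell expression data and uses them to simulate transcription-factor
(TF) perturbations in silico. This vignette is the package's account of the
underlying models, the parameters that matter, and the design decisions
taken where more than one reasonable choice existed.

## The model in brief

**Base GRN.** Candidate regulatory edges come from chromatin, not from
expression: accessible peaks are assigned to genes by TSS overlap
(`annotate_tss()`), extended to distal elements through co-accessibility
links (`select_cis_regions()`, default threshold 0.8), and scanned for TF
binding motifs (`scan_motifs()`). The result is a binary directed TF → target
candidate network. Constraining the regression to these candidates supplies
edge directionality that expression data alone cannot.

**Cluster-wise regression.** Within each cell cluster, the expression of a
target gene is modelled as a linear combination of its candidate TFs:

    x_j = sum_i b_ij x_i + c_j,        b_jj = 0

fitted per cluster so that context-dependent (cluster-specific) regulation
appears as cluster-specific coefficients. Two engines provide the
coefficient *distribution* rather than a point estimate:

* **bagging ridge** (default): an ensemble of closed-form ridge fits on
  bootstrap resamples of cells (50 bags, resampling 80 % of cells with
  replacement, penalty `alpha = 1`). The per-edge p-value is a two-sided
  one-sample t-test of the bag samples against zero, with the degenerate
  zero-variance cases mapped explicitly (nonzero mean → p = 0, zero mean →
  p = 1).
* **Bayesian ridge**: evidence maximization with Gamma(1e-6, 1e-6)
  hyperpriors on both precisions — a non-informative prior whose effective
  regularization strength is learned from the data. The posterior has no
  finite degrees of freedom attached, so the p-value uses the two-sided
  normal tail of mean/sd; this approximation is deliberate and documented
  here rather than pretending to an exact t reference.

**Signal propagation.** A perturbation sets one gene to a target value
(0 = knockout); the input shift `ΔX` is propagated by iterating
`Δ ← Δ · B` with, per round and in this fixed order: (1) matrix product,
(2) the perturbed gene's entry reset to the input shift, (3) simulated
levels floored at zero, (4) optional clipping into the wild-type per-gene
range (`clip_delta`). Three rounds are the default: coefficients are mostly
inside (−1, 1), so the shift magnitude saturates quickly, and the package's
monotone-saturation test asserts exactly that on non-negative networks. The
reset-before-floor order is a choice the package fixes and tests; on DAGs
the recursion provably equals the sum over directed paths of length ≤ n of
the product of edge coefficients, which is the oracle the test suite
checks against.

**From shifts to cell-state transitions.** For cell i with simulated shift
`d_i`, the probability of moving toward embedding neighbour j is

    p_ij = softmax_j( corr(d_i, x_j − x_i) / T ),   T = 0.05, k = 200

over the k nearest embedding neighbours. The expression offset is oriented
*from i toward j* — the same orientation as the embedding offset
`V_ij = e_j − e_i` used in the projection `V_i = Σ_j p_ij V_ij` — so a cell
moves toward neighbours that already resemble its post-perturbation state.
Degenerate correlations (all-zero shift, constant offset) are defined as 0.
KNN ties are broken by cell index, making every result reproducible.

**Grid vector field.** Per-cell vectors are summarized on an L × L grid
(default L = 40) by Gaussian kernel smoothing with bandwidth
`sigma = bounding-box diagonal / (2 L)`. The package reports the
weight-*normalized* average rather than the raw kernel sum: an unnormalized
sum scales with local cell density, which would make the field magnitude a
plot of density rather than of predicted movement. The kernel mass is kept
alongside, and grid points with mass below 1 % of the maximum are inactive
(zero vector, excluded from scores) so that no arrows appear in empty
embedding space.

**Perturbation score (PS).** Pseudotime is transferred to the same grid by
KNN regression (k = 30; robust for complex branching) or polynomial
regression (degree 3; suited to simple bifurcations), differentiated by
central differences per data-coordinate unit (one-sided at borders, masked
neighbours excluded), and compared with the simulation field through the
inner product `ps = ⟨v_sim, ∇t⟩`. Negative PS marks grid regions where the
perturbation opposes differentiation; TFs are ranked by the sum of |PS|
over negative-PS grids, optionally restricted to a lineage mask (majority
cluster per grid). The raw inner product is the default; a cosine
(normalized) mode exists but is off, since the raw product is what the
ranking statistic is defined on.

**Null model and cutoff.** Randomized GRNs permute coefficient values
within each target's nonzero edges and flip signs with probability 0.5 —
degree structure is preserved exactly, which keeps the null comparable to
the fitted network. The significance cutoff is the nearest-rank
(1 − FPR) quantile of null negative-PS sums (FPR default 0.01, i.e. the
99th percentile); nearest-rank avoids interpolation ambiguity.

**Markov density simulation.** Two row-stochastic matrices over cells —
one from the pseudotime-gradient vectors sampled at cell positions, one
from the perturbation vectors — are applied in alternation (differentiation
first), starting from cells below the 10 % pseudotime quantile. The default
is exact distribution propagation (deterministic and testable); a particle
mode exists and converges to the exact mode as particles grow. Using the
pseudotime gradient as the differentiation field is a documented choice:
RNA-velocity estimation is outside this package's scope, and the gradient
field is the differentiation signal the package already computes.

## The synthetic world

`make_world()` generates everything the pipeline consumes, with defaults
that are the package's reference study conditions: 100 genes of which 20
are TFs, 3 clusters × 500 cells, SEM residual noise sd 0.1, dropout 0.1,
3 regulators per target with coefficient magnitudes uniform in [0.2, 1]
and random signs. Two "lineage driver" TFs have expression programs that
double at each step of the cluster ordering and carry positive
coefficients, so their knockout demonstrably opposes the trajectory — the
phenotype the PS machinery is designed to detect. Expression follows the
linear structural equation model exactly (targets = intercept + TF effects
+ Gaussian noise), then a zero floor and Bernoulli dropout are applied;
the embedding is the first two PCs of `log1p(X)`; pseudotime is the
planted cluster order plus uniform jitter. TF levels are log-normal around
cluster-specific program means (spread `sdlog = 0.3`), giving the
within-cluster variance the regression needs for identifiability.

The toy genome plants each TF's distinct consensus motif (width 8,
containing at least one A and one T) in the promoter peak of each true
target, plus a copy in a distal enhancer linked at co-accessibility 0.9.
The background is C/G-only — a composition under which a consensus match
cannot arise by chance, verified explicitly at generation time — so motif
recovery is exact by construction and any false edge is a scanner bug.
Consensi are also checked against each other's reverse complements.

**What the world does not emulate** — and hence what passing tests do not
show about real data: negative-binomial count noise and per-gene
dispersion (only dropout + Gaussian residuals); TF–TF co-expression (TF
programs are independent log-normals); motif similarity between TFs
(consensi are engineered to be mutually exclusive); a realistic gene
universe (100 genes vs tens of thousands). The last two matter for the
scrambled-motif and no-base-GRN negative controls: with mutually exclusive
motifs the scrambled base GRN shares essentially no candidate pair with
the truth and scores at chance (AUROC ≈ 0.5), while the no-base fit on a
100-gene universe retains substantial coefficient mass on true TFs
(AUROC ≈ 0.8). On real data the two controls can order the other way
around — scrambling a real motif library keeps partial signal through
motif similarity, and a 10,000-gene no-base regression dilutes the true
regulators far more severely. The test suite asserts the
scrambled-above-no-base ordering all the same, and this section is the
record of why this world cannot produce it; the companion assertions
(matched ≥ 0.9, scrambled ≤ 0.6, matched > scrambled) all hold.

## Numerical choices and degenerate inputs

* Motif scoring: log2-odds of the pseudocounted frequency matrix
  (pseudocount 0.01) against a uniform 0.25 background; a site is accepted
  at ≥ 85 % of the motif's maximum attainable score (`score_frac = 0.85`).
  A fraction-of-max threshold is deterministic and needs no background
  genome, which is why it is used instead of an FPR-calibrated scan
  threshold. Ambiguous bases (N) contribute zero.
* TSS window: 1000 bp each side (proximal-promoter definition); the bulk
  10 kb variant is a parameter away (`window_bp = 10000`).
* Candidate regulators for target j: base-GRN TFs of j present in the
  expression matrix and expressed in ≥ 1 cell of the cluster, minus j
  itself. Targets with no candidates are skipped and listed.
* Clusters under 10 cells are skipped with a warning (`min_cells`);
  downsampling experiments lower this to 5 so tiny datasets still fit.
* KNN imputation: mean over k nearest cells (self included, default
  2.5 % of cells, ≥ 5) in 30-PC space of `log1p(X)`; only `imputed_X` is
  written, the raw matrix is never modified.
* Perturbation range check: a requested value outside the gene's observed
  range is refused as out-of-distribution; 0 is always legal, so a
  knockout can never be rejected. The per-gene maximum exceedance
  (percentage above the wild-type maximum) is reported with every
  simulation.
* A constant target gene yields zero coefficients and a flag rather than a
  spurious fit; a bootstrap bag that loses all variance in a column simply
  contributes zero for that column.

## Problem sizes in the test suite

Module tests run on a reduced world (120 cells per cluster); the
acceptance suite and `scripts/acceptance.R` run the reference conditions
(3 × 500 cells). The propagation oracle uses 200 random DAGs of ≤ 10
genes; null calibration uses 100 + 100 randomized-GRN simulations at full
size; the downsampling ladder re-fits at 400/200/100/50/25 cells. These
sizes were chosen so that every stochastic assertion has enough replicates
for a 3-sigma bound while the suite stays quick to iterate on.

## Known limitations

* Single-gene perturbations only (as in the underlying method); multi-gene
  interventions would be a small extension of `make_perturbation()`.
* The linear response model cannot express saturation or cooperativity;
  cluster-wise fitting recovers some context dependence but not
  within-cluster nonlinearity.
* Pseudotime, clustering and the 2D embedding are consumed as inputs; the
  quality of the PS ranking is bounded by the quality of the trajectory it
  is scored against.
* Eigenvector centrality on directed graphs can fail to converge on
  near-acyclic networks; the report falls back to the undirected
  projection and says so in the log.
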