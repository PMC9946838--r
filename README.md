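# grnflow

Cell-state-specific gene-regulatory-network (GRN) inference and in silico
transcription-factor (TF) perturbation for single-cell data.

Understanding which TFs govern a cell-identity transition usually requires
knockout experiments. grnflow addresses the computational half of that
problem for researchers working with scRNA-seq trajectories: it infers
cluster-specific GRNs from expression data constrained by chromatin-derived
candidate edges, simulates the transcriptome-wide effect of knocking out
(or overexpressing) any TF, projects that effect onto the 2D embedding as
cell-state transition vectors, and scores each TF by how strongly its loss
opposes the differentiation trajectory.

## The method

1. **Base GRN** — accessible peaks are assigned to genes by TSS overlap,
   extended through co-accessibility links (score >= 0.8) to distal
   elements, and scanned for TF-binding motifs (log-odds position-weight
   matrices, both strands). The result is a binary directed candidate
   network TF -> target.
2. **Cluster-wise regularized regression** — within each cell cluster,
   each target gene is modelled as

   `x_j = sum_i b_ij x_i + c_j` (b_jj = 0),

   fitted over the candidate TFs by a bagging ridge (bootstrap ensemble;
   coefficient mean, sd and a one-sample t-test p-value per edge) or a
   Bayesian ridge with Gamma(1e-6, 1e-6) hyperpriors.
3. **Signal propagation** — a perturbation vector `ΔX` (e.g. a knockout:
   the gene's expression set to 0) is propagated through the coefficient
   matrix, `Δ ← Δ·B`, for n = 3 rounds, with the perturbed gene held fixed
   and simulated levels floored at zero, estimating direct plus indirect
   shifts.
4. **Transition vectors** — per cell, the correlation of the simulated
   shift with expression offsets toward its k = 200 embedding neighbours
   is softmaxed (T = 0.05) into transition probabilities, whose weighted
   average of embedding offsets is a 2D cell-state transition vector;
   Gaussian kernel smoothing summarizes these on an L × L grid (L = 40).
5. **Perturbation score (PS)** — the inner product between the simulation
   field and the gradient of pseudotime on the same grid. Negative PS =
   predicted differentiation block. TFs are ranked by their negative PS
   sum against a randomized-GRN null with a nearest-rank FPR cutoff
   (default 0.01).
6. **Markov density** — alternating random walks under
   differentiation-derived and perturbation-derived transition matrices
   estimate where cell density accumulates after the perturbation.

A synthetic-world generator (linear structural equation model with planted
motifs in a toy genome) makes the whole pipeline testable offline, and
AUROC / early-precision-ratio scorers benchmark inferred networks against
binary ground truth.

## Worked example

```r
library(grnflow)

# a self-contained synthetic world: 100 genes (20 TFs), 3 clusters x 120
# cells, trajectory c1 -> c2 -> c3 driven by TF1/TF2
w <- make_world(seed = 3, n_cells_per_cluster = 120)

# base GRN from the world's chromatin fixtures
pg  <- annotate_tss(w$fixtures$peaks, w$fixtures$tss, window_bp = 0)
reg <- select_cis_regions(pg, w$fixtures$peaks, w$fixtures$coaccess,
                          threshold = 0.8)
bg  <- scan_motifs(reg, w$fixtures$genome, w$fixtures$motifs,
                   score_frac = 0.85)

# cluster-wise GRNs and a benchmark against the ground truth
grns  <- infer_grns(w$gem, bg, engine = "bagging", n_bags = 50, seed = 1)
bench <- benchmark_grns(grns, w$truth)
sprintf("AUROC %.3f, EPR %.2f", bench$auroc, bench$epr)
#> "AUROC 1.000, EPR 8.25"

# knockout of the lineage driver TF1, projected to a grid vector field
gem <- knn_impute(w$gem)
sim <- simulate_perturbation(gem, grns, "TF1", value = 0, k = 50, L = 20)
sim$field
#> grid_field: 20 x 20, 282 active grids, sigma = 0.201

# score the simulation field against the pseudotime gradient
pf <- gradient_field(pseudotime_to_grid(gem, field = sim$field))
ps <- perturbation_score(sim$field, pf)
sprintf("TF1 KO: negative PS sum %.1f, positive PS sum %.1f",
        ps$negative_ps_sum, ps$positive_ps_sum)
#> "TF1 KO: negative PS sum 71.4, positive PS sum 1.7"

# rank TFs with a randomized-GRN null
rk <- rank_tfs(gem, grns, c("TF1", "TF5", "TF12"), fpr = 0.05,
               n_null = 20, seed = 2, k = 50, L = 15)
rk$table
#>     tf neg_ps_sum   cutoff exceeds_cutoff
#> 1  TF1  39.966443 28.87719           TRUE
#> 2 TF12   4.958128 28.87719          FALSE
#> 3  TF5   4.123150 28.87719          FALSE
```

Reading the output: the benchmark says the inferred edge ranking separates
true from false candidate edges perfectly on this synthetic world (AUROC
1.0; EPR 8.25 means the top-k edges are 8.25× enriched over random). The
TF1 knockout produces a vector field almost entirely anti-parallel to the
pseudotime gradient (negative PS sum 71.4 vs positive 1.7): losing the
driver blocks differentiation, and `rank_tfs` flags TF1 — and only TF1 —
above the null cutoff.

A thin command-line interface over the same functions lives at
`inst/cli/grnflow.R` (subcommands `synth`, `build-base-grn`, `infer`,
`simulate`, `score`, `markov`, `netstats`, `benchmark`).

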