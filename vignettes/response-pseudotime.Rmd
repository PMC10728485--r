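---
title: "Response pseudotime and temporal decomposition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response pseudotime and temporal decomposition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimflow)
```

# The problem

Single-cell RNA-seq time courses of an acute perturbation — for instance
interferon-alpha stimulation of hematopoietic stem and progenitor cells
(HSPCs), sampled at control, 3 h, 24 h and 72 h — pose two linked analysis
problems that standard trajectory tools handle poorly:

1. **Cell identity shifts with treatment.** Marker genes used to annotate
   cell types (e.g. Sca-1 in HSPCs) are themselves induced by the
   stimulus, so clustering each timepoint independently conflates cell
   type with response state.
2. **Responses relax back to baseline.** Many response genes activate and
   then return toward their initial level. Unsupervised pseudotime methods
   that order cells by transcriptome dissimilarity place "recovered" cells
   near control cells, folding the time axis back on itself.

stimflow addresses both: identity is defined once, on unperturbed cells,
and propagated to treated cells by nearest-neighbour label transfer; and
the temporal axis is fitted *semi-supervised*, using the known capture
labels as the regression target, so the axis is anchored to the real arrow
of time even when expression is non-monotonic.

# Preprocessing model

Cells with a mitochondrial count fraction above 5% or fewer than 700
detected genes are removed (`filter_cells`); both thresholds are exposed
via `qc_thresholds`. Mitochondrial genes are recognised by a
case-insensitive `mt-` name prefix (mouse nomenclature; configurable).

Counts are normalized per cell to unit Euclidean norm (`l2_normalize_cells`)
rather than by library size: downstream statistics (standardization,
inner products in the regression) then act on comparable unit vectors.
Highly variable genes are ranked by the variance of analytic Pearson
residuals under a constant-expression null (`pearson_residual_hvgs`), with
overdispersion `theta = 100` and residual clipping at `sqrt(N)` — the
defaults of the analytic-residuals method; neither value is critical for
ranking at desk scale.

Per-gene standardization (`standardize_genes`) uses the **population
(1/N) variance** convention. Sample (1/(N-1)) standardization would only
rescale every downstream regression weight by the same per-gene constant,
but one convention has to be fixed for reproducibility; we fix 1/N.
Zero-variance genes cannot be standardized and are dropped with a report.

# Control-anchored annotation

`cluster_control` clusters the control subset: PCA (50 components), a
k-nearest-neighbour graph (k = 15) on the first 10 components, Leiden
community detection at resolution 0.8 (modularity objective, seeded).
`transfer_labels` then gives each treated cell the label most common among
its 15 nearest *control* cells by Euclidean distance in a shared
embedding. Majority ties are broken by the label of the nearest neighbour
carrying a tied label — the tie rule is not dictated by the method, we
chose it for determinism.

The embedding used for transfer is pluggable. Real multi-batch data
should use a dedicated integration method and pass its coordinates
directly; the built-in `joint_pca_embedding` (per-batch gene centering,
then joint PCA) is a deliberately simple fallback and documented as such,
not a reimplementation of any published integrator. Batch-corrected
coordinates are used *only* for transfer and layout — every downstream
statistic runs on the uncorrected data.

# Response genes

`run_de` tests each (cluster, treated timepoint) group against the same
cluster's control cells. The built-in engine forms pseudobulks (counts
summed per replicate × cluster × timepoint), computes log2 fold changes on
mean CPM + 1, tests per gene with a two-sided Welch t-test on
log2(CPM + 1) across replicates, and adjusts with Benjamini–Hochberg
within each contrast (contrasts are separate hypotheses families).
This is a pragmatic stand-in: it is replicate-aware and well calibrated
for planted-effect checks, but it is not a negative-binomial GLM. Results
from a dedicated engine (e.g. an edgeR likelihood-ratio pipeline) can be
supplied as a CSV via `engine = "external_table"` and flow through the
identical selection path.

`select_response_genes` keeps genes with adjusted p ≤ 0.05 **and**
|log2 FC| > 1 in at least one record, summarising each gene by its minimum
adjusted p over all records; `top_k_response_genes` keeps the 500 most
significant, breaking boundary ties by larger |log2 FC| and then gene
name. The fold-change threshold is interpreted as absolute (both induced
and repressed response genes are of interest), and the significance
threshold as "below 0.05".

# Change score and similarity score

Let `mu[i, j, t]` be the mean L2-normalized expression of gene *i* in
cluster *j* at timepoint *t* (`cluster_time_means`; a pseudo-cluster
`"all"` holds the global profile). Two complementary statistics decompose
global versus cluster-specific dynamics:

- **Change score** (`change_score`):
  `c[i, j] = sum_t |mu[i, j, t+1] - mu[i, j, t]|`, the total movement of
  the profile over the m = n − 1 intervals. It is nonnegative, zero
  exactly for constant profiles, and invariant to additive shifts.
- **Similarity score** (`similarity_score`): profiles are first min–max
  scaled to [0, 1] per (gene, cluster) (`pattern_minmax`), then
  `s[i, j] = 1 - sum_t |x[i, all, t] - x[i, j, t]| / n`, which is 1 when a
  cluster reproduces the global *shape* regardless of amplitude and 0 at
  maximal disagreement. Constant profiles cannot be min–max scaled; they
  are mapped to all-zero patterns and flagged degenerate rather than
  dropped, so every gene keeps a similarity row.

Genes are grouped by hierarchical clustering of their change-score vectors
with a flat cut at a cophenetic-distance threshold (default 3). The
linkage is genuinely a free choice — the reference analysis does not state
one — and group counts are sensitive to it; we default to Ward (`ward.D2`
on Euclidean distances) for stable, size-balanced groups and expose the
method. Group ids are renumbered by descending size purely for stable
output.

# Response pseudotime

The core model: with X the N × G matrix of L2-normalized, per-gene
standardized expression over the response genes, and T the per-cell
experimental time codes, find the weight vector W minimising
‖X·W − T‖². The fitted projection PT = X·W is the per-cell response
pseudotime. Choices and their reasons:

- **Time codes are equally spaced ordinals** (control, 3 h, 24 h, 72 h →
  0, 1, 2, 3), weighting the separation of each adjacent pair of
  timepoints equally. Using the raw hours would concentrate the fit on
  separating 24 h from 72 h. `timepoint_design(codes = ...)` accepts
  alternatives (e.g. log-hours).
- **No intercept.** Standardized X has centered columns, so an intercept
  would only absorb mean(T); fitted PT then averages 0 instead of
  mean(T), which shifts but never reorders cells. `intercept = TRUE` is
  available for comparison.
- **QR, not explicit inversion.** The closed form
  W = (XᵀX)⁻¹XᵀT is the analytical statement; computing it by explicit
  inversion is numerically fragile. We solve by QR, and fall back to the
  SVD minimum-norm solution (with a warning) when X is rank deficient —
  duplicated genes are a realistic cause.
- **N > G is enforced**: with more genes than cells the system is
  under-determined and PT becomes an arbitrary interpolator of T.

**Weight identifiability.** PT itself is well determined, but individual
weights are not when genes are collinear — and response genes are highly
collinear by construction (they all track the same response; with four
capture timepoints T spans few effective dimensions). A down-regulated
gene that exactly mirrors an up-regulated one makes the pair's weights
arbitrary up to a common shift. Interpreting the sign or magnitude of a
single gene's weight therefore requires the gene set to carry
non-redundant signal; our end-to-end test stages this deliberately by
giving up- and down-genes distinct midpoints and widths. PT, orderings,
and everything downstream of the ordering are unaffected by this caveat.

Cells are ordered by PT with a stable sort (`order_cells`, ties keep
input order). For pattern discovery, `smooth_pattern_matrix` averages each
gene over consecutive non-overlapping 100-cell bins along the ordering and
min–max scales per gene; a final partial bin is kept if it holds at least
half a bin and merged into the previous bin otherwise (the rule is ours:
it neither drops cells nor creates a noisy tiny bin). The smoothed
profiles are hierarchically clustered (`cluster_patterns`, default cut at
cophenetic distance 5.2, Ward linkage — same caveat as above about the
unstated linkage).

# Gene-set scores and profile curves

`score_gene_set` implements control-pool scoring: genes are binned into 25
equal-size bins by mean expression, one reference gene is drawn per set
gene from its bin (excluding the set), and the per-cell score is the set
mean minus the reference mean. The bin count and one-draw-per-gene rule
follow the routine's established convention; the seed is mandatory because
the reference is a random draw. On standardized input the binning is
effectively uniform (all means are 0), which is faithful to scoring on
scaled data.

`bootstrap_gene_profile` smooths one gene along pseudotime: 20 replicates,
each on a 50% subsample kept in pseudotime order, a centered rolling mean
of 600 cells sliding by one cell (50 for single-cluster profiles), and a
95% band as mean ± 1.96 × SE across replicates. Because subsamples differ,
replicate curves are aligned by interpolating onto a common 200-point grid
over pseudotime *rank fraction* — the alignment is our choice; each
window is placed at its mean rank fraction so a linear signal is
reproduced exactly. `loess_score_profile` does the analogous smoothing of
a gene-set score with first-order LOESS (30 replicates, span 0.3 by
default — the span is unstated in the reference analysis and exposed),
with direct-surface evaluation so linear signals are reproduced exactly on
the full grid.

# The simulator: a stated world

`simulate_dataset` emulates the reference validation setting, not real
10x data:

- four capture timepoints (0, 5, 10, 20), 250 cells each;
- hidden per-cell time = capture time + Gaussian asynchrony (SD 1.5),
  not clipped — trajectories are defined on all reals;
- 20 genes, each a sigmoid `S(t | alpha, beta) = 1/(1 + exp(-(t -
  alpha)/beta))` (monotonic) or `S(t) - S(t - t_switch)`
  (complex: activate then deactivate);
- per-gene min–max scaling over the sampled cells, then Gaussian
  expression noise (SD 0.05);
- a continuous mode draws hidden time uniformly on [0, 20]; capture
  labels are then assigned to the nearest capture timepoint (our choice —
  the supervised fit needs time codes, and nearest-timepoint binning is
  the natural discretisation of a uniform coverage).

The printed sigmoid in the reference has the exponent `(-t - alpha)/beta`;
we implement the standard increasing form `-(t - alpha)/beta` (midpoint at
alpha), since the reference's own activation curves increase with time —
we read the printed sign as a typo.

Parameter ranges for random gene panels are unstated in the reference;
once chosen, they are fixed: alpha ~ U(0, 20), beta ~ U(0.5, 3), t_switch
~ U(5, 15), with a 50/50 monotonic/complex and 50/50 up/down mix.
Down-regulated genes are `1 - value`, so both directions appear.

What the simulator does **not** model: UMI counting noise, dropout,
library-size variation, doublets, batch effects, or gene–gene
correlation beyond the shared time axis. A green recovery test therefore
establishes that the pseudotime regression recovers a hidden smooth
ordering under Gaussian noise and asynchrony — not that it is robust to
the count-level pathologies of real single-cell data.

```{r recovery}
sim <- simulate_dataset(simulation_spec(seed = 1))
model <- pseudotime_from_simulation(sim)
model$rho  # Spearman correlation of PT with the hidden true time
```

# Environment-driven substitutions

The simulator's on-disk spec and the CLI configuration use JSON
(`jsonlite`) rather than YAML: no YAML parser is available in the
package's pinned runtime, and the two formats are interchangeable for the
flat structures involved.

# Known limitations

- The pseudotime is linear in standardized expression; periodic or
  strongly nonlinear responses would need basis expansion of X, which is
  out of scope here.
- The built-in DE engine is not a substitute for a negative-binomial GLM
  on real counts; use the external-table path for publication-grade gene
  lists.
- Group/pattern counts from hierarchical clustering depend on the linkage,
  which the reference analysis leaves unstated; with a different linkage
  the same thresholds can give different group counts.
- Label transfer assumes the integrated embedding actually mixes
  timepoints; it cannot rescue a failed integration.
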