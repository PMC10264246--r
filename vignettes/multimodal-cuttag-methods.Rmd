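---
title: "Methods: multimodal single-cell CUT&Tag analysis with mmct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal single-cell CUT&Tag analysis with mmct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mmct` implements the computational arm of a trimodal single-cell CUT&Tag
experiment, in which barcoded Tn5 fusion proteins deposit modality-specific
adapters so that chromatin accessibility (ATAC), H3K27ac and H3K27me3 are
read out from the same cells. The pipeline covers: modality demultiplexing
of barcoded reads, fragment assembly and deduplication, simplified broad
peak calling, per-cell QC with Gaussian-mixture cell calling, sparse
bin/peak/gene-activity matrices with TF-IDF weighting, LSI embedding and
SNN graph clustering, Wilcoxon marker regions, MST pseudotime with
meta-region scores and two-wave stratification of H3K27me3 gains, and a
steady-state chromatin-velocity model that treats ATAC as the leading
("unspliced") layer and H3K27ac as the lagging ("spliced") layer. A
synthetic fragment generator with planted structure makes every stage
testable without external data; the numbered scripts under `analysis/` walk
the full pipeline on the generator's study conditions.

Read alignment, UMAP internals, weighted-nearest-neighbor embedding, CCA
integration with transcriptomic atlases and GO enrichment are out of scope;
any external 2-D embedding can be plugged into the visualization and
velocity-projection steps.

# The synthetic generator

`generate_dataset()` emulates the structure of a trimodal brain experiment
at desk scale:

* **Genome**: two 10-Mb chromosomes. Planted regions (2 kb each) are laid
  out on an even grid and shuffled across roles so no role clusters in one
  genomic stretch.
* **Cell populations**: `n_cell_types = 5` discrete types with 300 cells
  each, a 1,000-cell differentiation trajectory with latent time
  `t ~ U(0,1)`, and 300 low-depth background barcodes emulating empty
  droplets.
* **Programs**: each type gets 10 marker regions per modality (weight 1 for
  own-type cells). Trajectory loci follow logistic rises in latent time:
  40 *opening* regions gain ATAC at midpoints `t0 ~ U(0.2, 0.6)` and gain
  H3K27ac at `t0 + lag_delta` (default 0.2) — chromatin opening precedes
  acetylation; two sets of 40 *wave* regions gain H3K27me3 at midpoints
  0.25 and 0.7 — two sequential repressive waves. Wave loci carry no
  H3K27ac program: the repressive and active marks are mutually exclusive,
  which makes the H3K27ac/H3K27me3 pair anti-correlated across loci, as
  required for the velocity negative control. The logistic scale is 0.06
  pseudotime units (a transition occupies roughly ±3 scale units).
* **Counts**: fragment counts per (cell, region, modality) are Poisson with
  rate `depth_c * s * w_r(t_c) / Wbar`, where `depth_c` is the cell's
  lognormal depth (default meanlog `log(400)`, sdlog 0.4 — a deliberately
  desk-scale depth; all sizes here were chosen once for tractable runtimes
  and are stated as the package's study conditions), `Wbar` the mean total
  weight of the cell's class, and `s = (frip - rho) / (1 - rho)` the signal
  share solving for an expected in-region fraction equal to `frip_target`
  (default 0.3) after accounting for the genome fraction `rho` that uniform
  background fragments hit anyway. Background is allocated proportionally
  to depth so per-cell FrIP is approximately constant.
* **Reads**: `emit_fastq()` writes one R1/I1/I2/R2 quadruplet per fragment
  with the 36-8-48-36 read layout; the modality barcode is the R1 5'
  prefix, the cell barcode rides in I2, and coordinates are encoded in the
  read name so `fixture_align()` can stand in for an aligner. Exact
  duplicates are injected at `duplicate_rate` (default 0.12% of reads,
  a realistic linear-amplification duplicate level for this library
  design) and single-base barcode substitutions at
  `mismatch_inject_rate`. Coordinates are 0-based half-open everywhere
  (fragments-file convention).

What the generator does **not** emulate: nucleotide content, mappability
and GC structure, fragment-size periodicity, doublets, batch effects,
chromatin contamination between modalities, or genes with partially
overlapping programs. Passing tests therefore demonstrate the pipeline's
correctness and statistical behavior under a clean planted model, not
performance on real tissue.

# Demultiplexing

Barcodes are corrected against the whitelist by minimal Hamming distance
with `max_mismatch = 1` (the standard debarcoding tolerance). Ties at the
minimal distance and distances beyond the tolerance are *unassigned*:
dropping reads is preferred to cross-modality contamination. The whitelist
constructor warns when pairwise distances fall below `2*max_mismatch + 1`,
the threshold for unambiguous correction. The bundled synthetic barcodes
are stand-ins with pairwise distance equal to their length; they are not
published Tn5 barcode sequences. Deduplication keys on (chrom, start, end,
cell, modality), collapses survivors to `count = 1` and reports
multiplicity separately.

# Broad peaks and cell calling

`call_broad_peaks()` is a deliberately simplified analog of a broad-domain
caller, parameterized the way pseudobulk CUT&Tag data are commonly called
(local background 100 kb, broad cutoff q < 0.1, minimum length 1 kb, merge
gap 1 kb, duplicates collapsed): 200-bp bin counts are tested against
Poisson(max(global mean, centered local mean)), BH-corrected, and
significant bins merged. There is no fragment-size model, shifting, or
paired-end pileup — the repository needs a self-contained, testable analog
rather than a caller reimplementation.

Cell calling fits a two-component full-covariance Gaussian mixture to
(log10 unique fragments, FrIP) by EM. Initialization is a median split on
the depth axis with component moments from the halves — deterministic, so
fits reproduce without a seed; covariances carry a 1e-6 ridge; convergence
is a log-likelihood gain below 1e-6 (cap 500 iterations). The cell
component is the one with the larger mean on both axes (FrIP mean decides,
with a warning, if neither dominates), and a cell passes at posterior
> 0.5 — a probabilistic replacement for per-replicate manual gates.
Passing barcodes are intersected across modalities; the reported fraction
uses all cells identified in any modality as denominator, stated
explicitly because published pass rates often leave the denominator
implicit. On synthetic data, trajectory cells early in latent time
genuinely lack H3K27me3 signal, so their pass rate in that modality is
biologically depressed — the joint pass fraction reflects this.

# Matrices, LSI, clustering, markers

Counting is by interval overlap (a fragment spanning k bins increments k
entries), matching feature-matrix construction in the tagmentation
ecosystem; whether to count fragments or insertion ends is a known
ambiguity and overlap counting is pinned here. TF-IDF uses the log dialect
`x' = log(1 + 1e4 * tf * N/df)`; the literature contains several dialects
and one is pinned and tested. LSI is TF-IDF followed by a truncated SVD
(computed from the cell-cell Gram matrix, since cells ≪ features at this
scale); components with |correlation| > 0.75 to log depth are flagged and
optionally dropped — the first component usually tracks depth in sparse
chromatin data. Clustering builds a kNN graph (k = 20), weights edges by
neighborhood Jaccard overlap, prunes below 1/15 and optimizes modularity
with the multilevel (Louvain) algorithm under a fixed seed. At small per-
cluster sizes modularity at resolution 1 subdivides homogeneous groups;
the resolution is exposed and the analysis scripts use the default on the
study-condition sizes, where it recovers the planted types.

Markers are one-vs-rest Wilcoxon rank-sum tests per feature. The test uses
the exact null distribution when `min(n1, n2) <= 8` with no ties, else the
normal approximation with tie and continuity correction; the marker filter
is raw `p < 0.05` with `logFC > 0` and top 200 kept (BH-FDR available
behind a flag), with logFC computed on depth-normalized means with
pseudocount 1 for stability at sparse features. `capture_rate` is the
fraction of cluster cells with a nonzero count at the feature — the pinned
reading of "capture rate" as a per-cluster detection frequency. The
pseudobulk PCA pools each cluster's top-50 markers across modalities,
merges overlapping regions, depth-normalizes (counts per 10k, log1p) and
decomposes by PCA; profiles of the same population co-locate regardless of
the modality they came from. Clustering of the static types uses 15 LSI
components; trajectory analyses use 8 (see below).

# Trajectory, lag, and H3K27me3 waves

Pseudotime approximates a principal curve for a single unbranched lineage:
an MST over cluster centroids in the (concatenated-modality) LSI space,
the path from the start cluster to the farthest leaf, orthogonal projection
of cells onto the piecewise-linear path, and arc length rescaled to [0,1].
Terminal segments extend beyond the end centroids by at most one segment
length, so cells past the extreme centroids stay ordered without letting
off-path outliers stretch the scale. This is deterministic and adequate
for one lineage; branching lineages are out of scope. The trajectory
embedding concatenates all three modalities' bin matrices (the package's
stand-in for a weighted-nearest-neighbor joint space) and uses 8
components after dropping the depth component: the H3K27me3 waves extend
temporal discrimination late into the lineage where ATAC has saturated,
and additional components mostly add projection noise at these sizes.

The meta-region score is a per-cell sum over a selected region set of
depth-normalized, per-region max-scaled signal ("normalized score" is not
standardized in the field; this definition is pinned). When the matrix
contains only the scored regions, the per-cell depth must be supplied
explicitly — normalizing by the row totals of a region-restricted matrix
would divide out the very signal being scored. Curves over pseudotime are
loess fits (tricube local linear, span 0.75) with 95% bands from the local
standard error.

The ATAC-to-H3K27ac lag is the argmax of the normalized cross-correlation
of the two binned meta-score series, each overlap window mean-centered and
scale-normalized (template-matching NCC); centering globally instead
biases saturating curves toward zero lag. Positive lag means the first
series leads. In the acceptance analysis the series are binned on the
generator's latent time: a 0.2-unit lag is below the error scale of MST
pseudotime (Spearman ≈ 0.93 against truth), and binning by noisy
pseudotime mixes cells across bins, which synchronizes two series measured
on the same cells and attenuates the lag — the regression-dilution analog
for cross-modal timing. Pseudotime accuracy is assessed separately, on the
inferred ordering.

Wave stratification standardizes each region's pseudotime-binned profile
and k-means-clusters the rows with k = 2 (50 seeded restarts; with
restarts this is insensitive to the initialization scheme). Region timing
is the first pseudotime bin where the loess-smoothed profile exceeds half
its maximum — robust to sparsity — and labels are relabeled so wave 1 has
the earlier mean midpoint. Time-flat profiles degrade the standardization;
they trigger a warning and fall back to unstandardized profiles.

# Chromatin velocity

The steady-state (deterministic) model is implemented rather than wrapping
a published velocity package: the experiment specifies only the layer
mapping (ATAC to unspliced, H3K27ac to spliced) and default behavior, so
the model class is pinned and documented here. Gene activity counts
fragments over gene bodies extended 2 kb upstream of the TSS,
strand-aware (the window is unspecified in common practice and pinned
here). Both layers are size-normalized per cell — by the cell's **total
fragment count in that modality**, not by totals over the (small) gene
set, which rise along the trajectory and would distort every gene — and
kNN-smoothed (k = 30, self included) in the embedding. Per gene, the
steady-state ratio γ is the through-origin least-squares slope on the
union of the top and bottom 5% quantiles of s, clipped at zero, with the
extreme-set squared correlation reported as R²; velocity is the residual
`v = u - γ s`.

Velocity genes are selected before projection, as steady-state practice
requires, with three gates: at least 20 raw counts per layer, γ > 0, and a
squared u–s correlation on the **raw** normalized layers above
`max(0.01, qchisq(1 - 0.001/G, 1)/n)` for G genes and n cells. Two
numerical points matter here. First, selection must use the unsmoothed
layers: kNN smoothing collapses the effective degrees of freedom, every
smoothed gene shares the embedding's long-range structure, and background
genes would pass a smoothed-R² gate by chance. Second, the threshold is a
Bonferroni χ²(1) bound (under the null, `n·r²` is asymptotically χ²(1)),
so a background-only gene slips through with probability about 0.001 per
fit regardless of scale — a single leaked gene with monotone s is enough
to orient a projected field, so the gate is deliberately strict. On the
study conditions the planted dynamic genes exceed the bound several-fold.

Projection follows the transition-probability scheme: for each cell,
neighbor transition weights are proportional to `exp(cos(v_i, s_j - s_i) /
sigma)` with σ = 0.05, row-normalized; the field is the
probability-weighted mean displacement minus the unweighted neighborhood
mean (removing density drift); zero-velocity cells get zero vectors.
Drivers are ranked by R² times the variance of v. Alignment with the known
differentiation direction is the mean cosine between field vectors and the
local direction of increasing latent time (binned centroid path); its
one-sided test uses a **random-rotation null** — each vector rotated by an
independent uniform angle — because permuting vectors across cells
preserves the coupling between the field's global mean direction and the
path's mean direction and yields a biased null.

The negative control runs the identical pipeline with H3K27ac as the
leading and H3K27me3 as the lagging layer. Because the two marks are
mutually exclusive at planted loci, no gene shows a coherent u–s
relationship, the gene gate passes (essentially) nothing, and the field
carries no directional information: the anti-correlated pair fails to
predict the trajectory while ATAC/H3K27ac succeeds. Had an H3K27ac decay
program been planted at the H3K27me3 loci instead, H3K27ac would act as a
leading indicator of future H3K27me3 and a steady-state model would
(spuriously) orient the field — mutual exclusion, not mirrored dynamics,
is the faithful synthetic analog of this control.

# Problem sizes and runtime choices

All simulation sizes are fixed design choices of this package: 5 types ×
300 cells for clustering, 1,000 trajectory cells, 300 droplet barcodes,
~400 fragments per cell per modality, two 10-Mb chromosomes, 5-kb bins.
The FASTQ round trip in the analysis scripts runs on a reduced-cell
configuration with identical per-read rates, since emitted read text is
the one artifact whose size grows far faster than its information content.

# Known limitations

* The broad caller is an analog, not a MACS2 reimplementation; absolute
  peak boundaries will differ from published callers.
* MST-centroid pseudotime is coarser than iterative principal curves;
  cross-modal lags near or below its error scale require a better time
  axis (here, the generator's latent time) to quantify.
* The steady-state velocity model assumes a monotone precursor-product
  relationship; it is the wrong model for anti-correlated mark pairs by
  construction, which is exactly what the negative control demonstrates.
* The generator's clean planted programs mean the acceptance numbers are
  upper bounds on what the same pipeline would achieve on real tissue.
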