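# mmct — multimodal single-cell CUT&Tag analysis

Single-cell CUT&Tag with barcoded Tn5 fusion proteins reads out several
epigenomic modalities — chromatin accessibility (ATAC), the active mark
H3K27ac and the Polycomb mark H3K27me3 — from the *same* cells. `mmct` is an
R toolkit for the computational side of such experiments, for analysts who
have barcoded reads or fragments files and want to go from raw modality
barcodes to cell types, differentiation dynamics and chromatin velocity:

* **Demultiplexing** — route reads to modalities by their Tn5 barcode with
  one allowed mismatch (minimal Hamming distance; ties and misses dropped),
  assemble and deduplicate fragments, read/write 10x-style fragments files.
* **Peaks & cell calling** — a simplified broad-domain caller (Poisson bins,
  local λ over 100 kb, BH q < 0.1, merge ≤ 1 kb, min length 1 kb), per-cell
  unique-fragment counts and FrIP, and a two-component Gaussian mixture on
  (log10 n, FrIP) fit by EM to separate cells from empty droplets, with
  passing cells intersected across modalities.
* **Matrices & clustering** — sparse cells × features matrices over 5-kb
  bins, peaks or gene activities; TF-IDF `x' = log(1 + 10^4 · tf · N/df)`;
  LSI (truncated SVD with depth-component flagging); SNN graph clustering;
  one-vs-rest Wilcoxon markers (exact null for small groups) with capture
  rates; pseudobulk PCA over pooled top markers.
* **Trajectory** — MST-over-centroids pseudotime, per-cell meta-region
  scores with loess curves, normalized cross-correlation lag between
  modalities, and k = 2 stratification of H3K27me3-gaining regions into two
  temporal waves.
* **Chromatin velocity** — the steady-state model with ATAC as the
  "unspliced" layer *u* and H3K27ac as the "spliced" layer *s*: per gene,
  γ is the through-origin slope on the extreme quantiles of *s* and the
  velocity is the residual **v = u − γ·s**; fields are projected onto a 2-D
  embedding via cosine transition kernels, drivers ranked by R² · var(v),
  and the anti-correlated H3K27ac/H3K27me3 pair serves as a negative
  control that should *not* predict the trajectory.
* **Synthetic data** — a generator that plants cell types, an
  ATAC→H3K27ac lag and two H3K27me3 waves with controllable depth, FrIP,
  duplicates and barcode errors, plus FASTQ emission and an alignment
  stand-in, so the entire pipeline is testable end to end with known truth.

The methods vignette (`vignettes/multimodal-cuttag-methods.Rmd`) documents
every model, default and numerical choice.

## Worked example

The numbered scripts under `analysis/` run the whole pipeline on the
generator's study conditions (5 cell types × 300 cells, 1,000 trajectory
cells, 300 empty-droplet barcodes, 3 modalities) and write their tables
under `results/`. For example:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_trajectory_waves.R
```

prints

```
mean ATAC FrIP vs truth regions (static cells): 0.303 (target 0.30)
...
pseudotime over 1000 cells (9 clusters): Spearman rho vs latent time = 0.941
chromatin opening leads H3K27ac gain by 4 of 20 latent-time bins (planted 4)
two H3K27me3 waves: assignment accuracy 100.0%, midpoints 0.26 / 0.66 (planted 0.25 / 0.70)
```

meaning: the generator hit its signal-to-noise target; MST pseudotime
reconstructs the latent differentiation order; the meta-region score of
chromatin opening leads the H3K27ac score by the planted 0.2 pseudotime
units (4 bins of 20); and k-means over the H3K27me3 region profiles
recovers the two planted repressive waves and their onset times.
`analysis/05_velocity.R` then reports the chromatin-velocity field aligned
with the differentiation direction (mean cosine 0.68, p = 0.005 against a
rotation null) while the H3K27ac/H3K27me3 negative control selects no
velocity genes and shows no alignment (p = 1).

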