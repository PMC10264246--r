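# Shared fixtures are generated once per test run and cached; everything is
# seeded, nothing is read from disk.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# Desk-scale dataset for module tests.
small_config <- function(...) {
  synthetic_config(n_cell_types = 3, n_static_cells_per_type = 60,
                   n_trajectory_cells = 200, n_background_barcodes = 80,
                   depth_log_mean = log(300), seed = 42, ...)
}
small_dataset <- function() cached("small", generate_dataset(small_config()))

# Full study-condition dataset (generator defaults) for the acceptance suite.
default_dataset <- function() cached("default", generate_dataset(synthetic_config()))

cells_of <- function(ds, class) {
  ds$truth$cells$cell[ds$truth$cells$class == class]
}

latent_time <- function(ds, barcodes) {
  ds$truth$cells$t[match(barcodes, ds$truth$cells$cell)]
}

type_of <- function(ds, barcodes) {
  ds$truth$cells$type[match(barcodes, ds$truth$cells$cell)]
}

modality_depth <- function(ds, modality, barcodes) {
  as.numeric(table(factor(ds$fragments[[modality]]$cell, levels = barcodes)))
}

# Concatenated-modality 5-kb bin matrix (the multimodal embedding input).
combined_bin_matrix <- function(ds, barcodes, key) {
  cached(key, {
    genome <- ds$truth$config$genome
    bms <- lapply(ds$fragments, function(f) build_bin_matrix(f, genome, 5000, barcodes))
    modality_matrix(do.call(cbind, lapply(bms, function(b) b$counts)),
                    do.call(rbind, lapply(bms, function(b) b$features)),
                    barcodes, "combined")
  })
}

# Static-cell bin matrices per modality for the study-condition dataset.
default_static_matrices <- function() {
  cached("default_static_mats", {
    ds <- default_dataset()
    st <- cells_of(ds, "static")
    genome <- ds$truth$config$genome
    lapply(setNames(nm = names(ds$fragments)), function(m)
      build_bin_matrix(ds$fragments[[m]], genome, 5000, st))
  })
}

# Trajectory-cell bundle: combined LSI embedding, clusters, pseudotime inputs.
default_trajectory <- function() {
  cached("default_traj", {
    ds <- default_dataset()
    tr <- cells_of(ds, "trajectory")
    comb <- combined_bin_matrix(ds, tr, "default_comb_bm")
    emb <- lsi(comb, d = 8, drop_depth = TRUE)
    labels <- snn_cluster(emb, seed = 7)
    tt <- latent_time(ds, tr)
    start <- names(which.min(tapply(tt, labels, mean)))
    list(ds = ds, cells = tr, t = tt, emb = emb, labels = labels, start = start)
  })
}

## ---- independent brute-force oracles ----

# quadratic all-pairs >= 1 bp interval overlap
overlaps_1bp <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

frip_oracle <- function(fragments, peaks_df) {
  hit <- vapply(seq_len(nrow(fragments)), function(i) {
    any(fragments$chrom[i] == peaks_df$chrom &
          overlaps_1bp(fragments$start[i], fragments$end[i],
                       peaks_df$start, peaks_df$end))
  }, logical(1))
  tapply(hit, fragments$cell, mean)
}

count_matrix_oracle <- function(fragments, intervals, cells) {
  out <- matrix(0, length(cells), nrow(intervals))
  for (i in seq_len(nrow(fragments))) {
    ci <- match(fragments$cell[i], cells)
    if (is.na(ci)) next
    for (j in seq_len(nrow(intervals))) {
      if (fragments$chrom[i] == intervals$chrom[j] &&
          overlaps_1bp(fragments$start[i], fragments$end[i],
                       intervals$start[j], intervals$end[j])) {
        out[ci, j] <- out[ci, j] + 1
      }
    }
  }
  out
}

random_fragments <- function(n, genome = c(chrA = 10000, chrB = 8000),
                             cells = paste0("cell", 1:4)) {
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - 300))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + sample(50:250, n, replace = TRUE)),
             cell = sample(cells, n, replace = TRUE),
             modality = "ATAC", count = 1L, stringsAsFactors = FALSE)
}

random_intervals <- function(n, genome = c(chrA = 10000, chrB = 8000)) {
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - 500))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + sample(100:400, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
wilcoxon_enum_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(r), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  # two-sided: as extreme or more extreme in either direction (symmetric null)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
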