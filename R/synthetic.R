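MODALITIES <- c("ATAC", "H3K27ac", "H3K27me3")

#' Modality (Tn5) barcode whitelist for synthetic data
#'
#' Returns one barcode per modality with maximal pairwise Hamming distance
#' (equal to the barcode length), so single-base errors are always
#' correctable. These are synthetic stand-ins, not the published Tn5 barcode
#' oligonucleotide sequences.
#'
#' @param length_bp barcode length in bases.
#' @return named character vector, one barcode per modality.
#' @export
synthetic_barcode_map <- function(length_bp = 8) {
  pats <- c("ACGT", "CGTA", "GTAC")
  bc <- vapply(pats, function(p) {
    paste0(rep(strsplit(p, "")[[1]], length.out = length_bp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  setNames(bc, MODALITIES)
}

#' Configuration for the synthetic multimodal fragment generator
#'
#' The generator emulates a trimodal single-cell CUT&Tag experiment (ATAC,
#' H3K27ac, H3K27me3 sharing cell barcodes): discrete cell types with
#' modality-specific marker regions, a differentiation trajectory in which
#' chromatin opening precedes H3K27ac gain by `lag_delta` pseudotime units,
#' and two temporally distinct waves of H3K27me3 gain. Wave loci carry no
#' H3K27ac program (the two marks are mutually exclusive), so repressive and
#' active marks are anti-correlated across loci, as required for velocity
#' negative controls. Low-depth background barcodes emulate empty droplets
#' for cell-calling tests.
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param n_cell_types,n_static_cells_per_type discrete cell-type structure.
#' @param n_trajectory_cells cells with latent time t ~ U(0,1).
#' @param markers_per_type_per_modality planted marker regions per type and
#'   modality.
#' @param n_opening_regions trajectory loci that open (ATAC) then gain
#'   H3K27ac after `lag_delta`.
#' @param n_wave_regions H3K27me3-gaining loci per wave.
#' @param region_length_bp planted region width.
#' @param depth_log_mean,depth_log_sd lognormal fragments-per-cell parameters;
#'   scalars or length-3 vectors named by modality.
#' @param frip_target expected fraction of a cell's fragments inside planted
#'   regions (fraction of reads in peaks against truth).
#' @param lag_delta pseudotime lag between ATAC opening and H3K27ac gain
#'   midpoints.
#' @param wave1_midpoint,wave2_midpoint pseudotime midpoints of the two
#'   H3K27me3 gain waves; must satisfy wave1 < wave2.
#' @param logistic_scale steepness scale of all logistic rises (pseudotime
#'   units).
#' @param n_background_barcodes empty-droplet barcodes (background only).
#' @param background_depth_log_mean,background_depth_log_sd depth of the
#'   background barcodes.
#' @param barcode_length_bp modality barcode length.
#' @param cell_barcode_length_bp droplet barcode length.
#' @param duplicate_rate fraction of extra duplicate reads injected by
#'   [emit_fastq()].
#' @param mismatch_inject_rate fraction of reads whose modality barcode gets a
#'   single substitution in [emit_fastq()].
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a validated `mmct_config` list.
#' @export
synthetic_config <- function(genome = c(chr1 = 1e7, chr2 = 1e7),
                             n_cell_types = 5,
                             n_static_cells_per_type = 300,
                             n_trajectory_cells = 1000,
                             markers_per_type_per_modality = 10,
                             n_opening_regions = 40,
                             n_wave_regions = 40,
                             region_length_bp = 2000,
                             depth_log_mean = log(400),
                             depth_log_sd = 0.4,
                             frip_target = 0.3,
                             lag_delta = 0.2,
                             wave1_midpoint = 0.25,
                             wave2_midpoint = 0.7,
                             logistic_scale = 0.06,
                             n_background_barcodes = 300,
                             background_depth_log_mean = log(40),
                             background_depth_log_sd = 0.5,
                             barcode_length_bp = 8,
                             cell_barcode_length_bp = 16,
                             duplicate_rate = 0.0012,
                             mismatch_inject_rate = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_cell_types = n_cell_types,
              n_static_cells_per_type = n_static_cells_per_type,
              markers_per_type_per_modality = markers_per_type_per_modality,
              region_length_bp = region_length_bp,
              barcode_length_bp = barcode_length_bp)
  if (any(counts <= 0)) stopf("all structural counts must be > 0")
  if (n_trajectory_cells < 0 || n_background_barcodes < 0 ||
      n_opening_regions < 0 || n_wave_regions < 0)
    stopf("cell/region counts must be >= 0")
  if (n_static_cells_per_type * n_cell_types + n_trajectory_cells == 0)
    stopf("configuration generates zero cells")
  if (frip_target < 0 || frip_target > 1) stopf("frip_target must be in [0,1]")
  if (lag_delta < 0 || lag_delta > 1) stopf("lag_delta must be in [0,1]")
  if (wave1_midpoint >= wave2_midpoint) stopf("wave1_midpoint must be < wave2_midpoint")
  if (is.null(names(genome)) || any(genome <= 0)) stopf("genome must be named positive lengths")
  for (f in c("depth_log_mean", "depth_log_sd")) {
    v <- cfg[[f]]
    if (length(v) == 1) v <- setNames(rep(v, 3), MODALITIES)
    if (!all(MODALITIES %in% names(v))) stopf("%s must be scalar or named by modality", f)
    cfg[[f]] <- v[MODALITIES]
  }
  n_regions <- n_cell_types * markers_per_type_per_modality * 3 +
    n_opening_regions + 2L * n_wave_regions
  if (n_regions * region_length_bp * 2 > sum(genome))
    stopf("planted regions do not fit within the genome")
  structure(cfg, class = "mmct_config")
}

# Lay out n non-overlapping intervals evenly over the genome (deterministic).
place_regions <- function(genome, n, len) {
  total <- sum(genome)
  stride <- floor(total / n)
  if (stride <= len) stopf("planted regions do not fit within the genome")
  offs <- (seq_len(n) - 1) * stride + floor((stride - len) / 2)
  bounds <- cumsum(c(0, genome))
  chrom_idx <- findInterval(offs, bounds, rightmost.closed = FALSE)
  data.frame(chrom = names(genome)[chrom_idx],
             start = as.integer(offs - bounds[chrom_idx]),
             end = as.integer(offs - bounds[chrom_idx] + len),
             stringsAsFactors = FALSE)
}

# Per-cell x per-region logistic weights for one modality.
region_weights <- function(cells, regions, scale) {
  W <- matrix(0, nrow(cells), nrow(regions))
  if (!nrow(cells) || !nrow(regions)) return(W)
  st <- cells$class == "static"
  tr <- cells$class == "trajectory"
  for (j in seq_len(nrow(regions))) {
    r <- regions[j, ]
    if (r$role == "static-marker") {
      W[st & cells$type == r$type, j] <- 1
    } else {
      W[tr, j] <- plogis((cells$t[tr] - r$t0) / scale)
    }
  }
  W
}

#' Generate a synthetic multimodal fragment dataset
#'
#' Fragment counts per (cell, region, modality) are Poisson with rate
#' `depth_c * s * w_r(t_c) / Wbar`, where `w_r` is 1 for a cell's own static
#' markers and a logistic rise in latent time for trajectory loci (midpoint
#' `t0` for ATAC opening, `t0 + lag_delta` for the H3K27ac gain,
#' `wave1_midpoint`/`wave2_midpoint` for H3K27me3); `Wbar` is the mean total weight of the
#' cell's class so that the expected in-region fraction of fragments equals
#' `frip_target`. The signal share `s = (frip_target - rho) / (1 - rho)`
#' corrects for the fraction `rho` of the genome covered by planted regions,
#' which uniform background fragments also hit. Fragment positions are
#' uniform within regions (signal) or the genome (background); everything is
#' deterministic given `config$seed`.
#'
#' @param config an [synthetic_config()] object.
#' @return an `mmct_dataset`: `fragments` (named list of per-modality
#'   fragment data.frames) and `truth` (cell table with class/type/latent
#'   time/depths, region table with roles and onset midpoints, barcode map,
#'   config, and an `expected_rate(cell, region_id, modality)` closure).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "mmct_config"))
  with_seed(config$seed, {
    genome <- config$genome
    K <- config$n_cell_types
    M <- config$markers_per_type_per_modality

    ## ---- region table ----
    n_static <- K * M * 3
    n_intervals <- n_static + config$n_opening_regions + config$n_wave_regions * 2
    pos <- place_regions(genome, n_intervals, config$region_length_bp)
    pos <- pos[sample.int(n_intervals), , drop = FALSE]  # interleave roles
    rownames(pos) <- NULL
    i <- 0L
    take <- function(n) { idx <- pos[i + seq_len(n), , drop = FALSE]; i <<- i + n; idx }
    static <- take(n_static)
    static$role <- "static-marker"
    static$modality <- rep(MODALITIES, each = K * M)
    static$type <- rep(rep(paste0("type", seq_len(K)), each = M), times = 3)
    static$t0 <- NA_real_
    open_iv <- take(config$n_opening_regions)
    opening <- acetyl <- open_iv
    t0_open <- runif(config$n_opening_regions, 0.2, 0.6)
    opening$role <- "opening";    opening$modality <- "ATAC";    opening$t0 <- t0_open
    acetyl$role <- "acetyl-gain"; acetyl$modality <- "H3K27ac";  acetyl$t0 <- t0_open + config$lag_delta
    opening$type <- acetyl$type <- NA_character_
    wv <- list()
    for (w in 1:2) {
      gain <- take(config$n_wave_regions)
      gain$role <- paste0("wave", w)
      gain$modality <- "H3K27me3"
      gain$t0 <- if (w == 1) config$wave1_midpoint else config$wave2_midpoint
      gain$type <- NA_character_
      wv[[w]] <- gain
    }
    regions <- rbind(static, opening, acetyl, do.call(rbind, wv))
    regions$region_id <- sprintf("region_%04d", seq_len(nrow(regions)))
    rownames(regions) <- NULL

    ## ---- cell table ----
    n_sig <- K * config$n_static_cells_per_type + config$n_trajectory_cells
    n_cells <- n_sig + config$n_background_barcodes
    repeat {
      bc <- random_dna(n_cells, config$cell_barcode_length_bp)
      if (!anyDuplicated(bc)) break
    }
    cells <- data.frame(
      cell = bc,
      class = rep(c("static", "trajectory", "background"),
                  c(K * config$n_static_cells_per_type, config$n_trajectory_cells,
                    config$n_background_barcodes)),
      type = c(rep(paste0("type", seq_len(K)), each = config$n_static_cells_per_type),
               rep(NA_character_, config$n_trajectory_cells + config$n_background_barcodes)),
      t = NA_real_, stringsAsFactors = FALSE)
    cells$t[cells$class == "trajectory"] <- runif(config$n_trajectory_cells)
    for (m in MODALITIES) {
      d <- numeric(n_cells)
      sig <- cells$class != "background"
      d[sig] <- rlnorm(sum(sig), config$depth_log_mean[[m]], config$depth_log_sd[[m]])
      d[!sig] <- rlnorm(sum(!sig), config$background_depth_log_mean,
                        config$background_depth_log_sd)
      cells[[paste0("depth_", m)]] <- d
    }

    ## ---- signal share ----
    iv <- unique(regions[c("chrom", "start", "end")])
    rho <- sum(iv$end - iv$start) / sum(genome)
    s_frac <- (config$frip_target - rho) / (1 - rho)
    if (s_frac < 0) {
      warnf("frip_target below background region coverage; signal share clamped to 0")
      s_frac <- 0
    }

    ## ---- fragments ----
    frag_len <- function(n, max_len) {
      pmin(pmax(round(rnorm(n, 200, 50)), 100L), max_len)
    }
    normalizers <- list()
    frags <- list()
    for (m in MODALITIES) {
      reg_m <- regions[regions$modality == m, , drop = FALSE]
      W <- region_weights(cells, reg_m, config$logistic_scale)
      wbar <- setNames(numeric(2), c("static", "trajectory"))
      rows <- list()
      depth <- cells[[paste0("depth_", m)]]
      for (cls in c("static", "trajectory")) {
        ci <- which(cells$class == cls)
        if (!length(ci) || !nrow(reg_m)) next
        Wc <- W[ci, , drop = FALSE]
        wbar[cls] <- mean(rowSums(Wc))
        if (wbar[cls] == 0) next
        rates <- depth[ci] * s_frac * Wc / wbar[cls]
        cnt <- matrix(rpois(length(rates), rates), nrow = length(ci))
        nz <- which(cnt > 0, arr.ind = TRUE)
        if (nrow(nz)) {
          n_rep <- cnt[nz]
          cell_idx <- rep(ci[nz[, 1]], n_rep)
          reg_idx <- rep(nz[, 2], n_rep)
          fl <- frag_len(length(cell_idx), config$region_length_bp)
          off <- floor(runif(length(cell_idx)) *
                         (reg_m$end[reg_idx] - reg_m$start[reg_idx] - fl + 1))
          rows[[cls]] <- data.frame(
            chrom = reg_m$chrom[reg_idx],
            start = as.integer(reg_m$start[reg_idx] + off),
            end = as.integer(reg_m$start[reg_idx] + off + fl),
            cell = cells$cell[cell_idx], stringsAsFactors = FALSE)
        }
      }
      # uniform background, allocated proportionally to depth
      bg_mult <- ifelse(cells$class == "background", 1, 1 - s_frac)
      n_bg <- rpois(n_cells, depth * bg_mult)
      cell_idx <- rep(seq_len(n_cells), n_bg)
      nb <- length(cell_idx)
      if (nb) {
        chrom_idx <- sample.int(length(genome), nb, replace = TRUE,
                                prob = genome / sum(genome))
        fl <- frag_len(nb, 450L)
        st <- floor(runif(nb) * (genome[chrom_idx] - fl))
        rows[["background"]] <- data.frame(
          chrom = names(genome)[chrom_idx],
          start = as.integer(st), end = as.integer(st + fl),
          cell = cells$cell[cell_idx], stringsAsFactors = FALSE)
      }
      fr <- do.call(rbind, rows)
      if (is.null(fr)) fr <- data.frame(chrom = character(), start = integer(),
                                        end = integer(), cell = character())
      fr$modality <- m
      fr$count <- 1L
      rownames(fr) <- NULL
      frags[[m]] <- fr
      normalizers[[m]] <- wbar
    }

    truth <- list(cells = cells, regions = regions,
                  barcode_map = synthetic_barcode_map(config$barcode_length_bp),
                  rho = rho, s_frac = s_frac, normalizers = normalizers,
                  config = config)
    truth$expected_rate <- local({
      tr <- truth
      function(cell, region_id, modality) {
        ci <- match(cell, tr$cells$cell)
        reg_m <- tr$regions[tr$regions$modality == modality, , drop = FALSE]
        rj <- match(region_id, reg_m$region_id)
        if (is.na(ci) || is.na(rj)) stopf("unknown cell or region")
        cls <- tr$cells$class[ci]
        if (cls == "background") return(0)
        w <- region_weights(tr$cells[ci, , drop = FALSE], reg_m[rj, , drop = FALSE],
                            tr$config$logistic_scale)[1, 1]
        wbar <- tr$normalizers[[modality]][[cls]]
        if (wbar == 0) return(0)
        tr$cells[[paste0("depth_", modality)]][ci] * tr$s_frac * w / wbar
      }
    })
    structure(list(fragments = frags, truth = truth), class = "mmct_dataset")
  })
}

#' Empirical fraction of fragments in planted truth regions
#'
#' @param fragments fragment data.frame.
#' @param regions region table (or GroundTruth region table).
#' @return named per-cell vector of in-region fractions.
#' @export
empirical_frip <- function(fragments, regions) {
  fr <- df_to_granges(fragments)
  rg <- GenomicRanges::reduce(df_to_granges(unique(regions[c("chrom", "start", "end")])))
  hit <- IRanges::overlapsAny(fr, rg)
  tapply(hit, fragments$cell, mean)
}

#' Emit barcoded FASTQ reads for a synthetic dataset
#'
#' One read quadruplet (R1, I1, I2, R2) per fragment, plus
#' `round(duplicate_rate * n)` injected exact duplicates. R1 starts with the
#' modality barcode (single-base substitutions injected at
#' `mismatch_inject_rate`); I2 carries the cell barcode; genomic coordinates
#' are encoded in the read name for [fixture_align()]. Default read lengths
#' are 36-8-48-36 (R1-I1-I2-R2).
#'
#' @param dataset an `mmct_dataset`.
#' @param dir output directory.
#' @param barcode_map modality -> barcode; default from the dataset truth.
#' @param layout named read lengths `c(r1=, i1=, i2=, r2=)`.
#' @param gzip write gzip-compressed FASTQ.
#' @param duplicate_rate,mismatch_inject_rate,seed default from the dataset
#'   config.
#' @return list with file `paths`, `n_reads`, the per-read truth table
#'   (`reads`: name, modality, cell, n_substitutions) and the injected
#'   mismatch table.
#' @export
emit_fastq <- function(dataset, dir,
                       barcode_map = dataset$truth$barcode_map,
                       layout = c(r1 = 36, i1 = 8, i2 = 48, r2 = 36),
                       gzip = FALSE,
                       duplicate_rate = dataset$truth$config$duplicate_rate,
                       mismatch_inject_rate = dataset$truth$config$mismatch_inject_rate,
                       seed = dataset$truth$config$seed) {
  fr <- do.call(rbind, dataset$fragments)
  miss <- setdiff(unique(fr$modality), names(barcode_map))
  if (length(miss)) stopf("barcode_map lacks modality: %s", paste(miss, collapse = ", "))
  bl <- nchar(barcode_map[[1]])
  with_seed(seed, {
    n0 <- nrow(fr)
    n_dup <- round(duplicate_rate * n0)
    if (n_dup > 0) fr <- rbind(fr, fr[sample.int(n0, n_dup, replace = TRUE), ])
    n <- nrow(fr)
    name <- sprintf("MMCT:%d:%s:%d:%d:%s:%s", seq_len(n), fr$chrom, fr$start,
                    fr$end, fr$cell, fr$modality)
    bc <- unname(barcode_map[fr$modality])
    mut <- runif(n) < mismatch_inject_rate
    bc_obs <- bc
    if (any(mut)) bc_obs[mut] <- inject_substitutions(bc[mut], 1)
    r1 <- paste0(bc_obs, random_dna(n, layout[["r1"]] - bl))
    i1 <- strrep("A", layout[["i1"]])
    pad <- layout[["i2"]] - nchar(fr$cell[1])
    i2 <- paste0(fr$cell, strrep("T", max(pad, 0)))
    r2 <- random_dna(n, layout[["r2"]])
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    paths <- file.path(dir, paste0(c("R1", "I1", "I2", "R2"), ext))
    names(paths) <- c("R1", "I1", "I2", "R2")
    wr <- function(path, seqs, qlen) {
      con <- if (gzip) gzfile(path, "w") else file(path, "w")
      on.exit(close(con))
      writeLines(paste0("@", name, "\n", seqs, "\n+\n", strrep("I", qlen)), con)
    }
    wr(paths["R1"], r1, layout[["r1"]])
    wr(paths["I1"], i1, layout[["i1"]])
    wr(paths["I2"], i2, layout[["i2"]])
    wr(paths["R2"], r2, layout[["r2"]])
    reads <- data.frame(name = name, modality = fr$modality, cell = fr$cell,
                        n_substitutions = as.integer(mut), stringsAsFactors = FALSE)
    injected <- data.frame(name = name[mut], modality = fr$modality[mut],
                           barcode_true = bc[mut], barcode_observed = bc_obs[mut],
                           stringsAsFactors = FALSE)
    list(paths = paths, n_reads = n, reads = reads, injected_mismatches = injected)
  })
}

#' Read a FASTQ file into a name/sequence table
#'
#' @param path FASTQ path (gzip supported).
#' @return data.frame with `name` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(name = names(x), seq = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Recover fragment coordinates from synthetic FASTQ (alignment stand-in)
#'
#' Parses the coordinates encoded in read names by [emit_fastq()]; stands in
#' for a read aligner so downstream stages can be tested end to end.
#' Malformed read names are skipped with a single counted warning.
#'
#' @param r1_path R1 FASTQ path.
#' @param i2_path optional I2 FASTQ path; when given the cell barcode is taken
#'   from the I2 sequence rather than the read name.
#' @param barcode_length modality barcode length at the R1 prefix.
#' @param cell_barcode_length cell barcode length at the I2 prefix.
#' @return data.frame of (chrom, start, end, cell, barcode) records, with the
#'   skip count in `attr(, "n_skipped")`.
#' @export
fixture_align <- function(r1_path, i2_path = NULL, barcode_length = 8,
                          cell_barcode_length = 16) {
  r1 <- read_fastq(r1_path)
  parts <- strsplit(r1$name, ":", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 6 && p[1] == "MMCT" && !is.na(suppressWarnings(as.integer(p[4])))
  }, logical(1))
  n_skip <- sum(!ok)
  if (n_skip) warnf("fixture_align: skipped %d malformed read name(s)", n_skip)
  parts <- parts[ok]
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 3),
    start = as.integer(vapply(parts, `[`, character(1), 4)),
    end = as.integer(vapply(parts, `[`, character(1), 5)),
    cell = vapply(parts, `[`, character(1), 6),
    barcode = substr(r1$seq[ok], 1, barcode_length),
    stringsAsFactors = FALSE)
  if (!is.null(i2_path)) {
    i2 <- read_fastq(i2_path)
    out$cell <- substr(i2$seq[ok], 1, cell_barcode_length)
  }
  attr(out, "n_skipped") <- n_skip
  out
}
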