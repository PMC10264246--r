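test_that("config invariants are enforced", {
  expect_error(synthetic_config(frip_target = 1.2), "frip_target")
  expect_error(synthetic_config(wave1_midpoint = 0.8, wave2_midpoint = 0.3), "wave1")
  expect_error(synthetic_config(n_cell_types = 0), "counts")
  expect_error(synthetic_config(n_static_cells_per_type = 1, n_cell_types = 1,
                                n_trajectory_cells = 0,
                                genome = c(chr1 = 2e5),
                                region_length_bp = 2000), "fit within")
})

test_that("planted regions are disjoint, within bounds, with ordered waves", {
  ds <- small_dataset()
  reg <- ds$truth$regions
  genome <- ds$truth$config$genome
  expect_true(all(reg$end <= genome[reg$chrom]))
  expect_true(all(reg$start >= 0))
  gr <- GenomicRanges::reduce(df_to_granges(unique(reg[c("chrom", "start", "end")])))
  expect_equal(sum(GenomicRanges::width(gr)),
               nrow(unique(reg[c("chrom", "start", "end")])) *
                 ds$truth$config$region_length_bp)
  # wave separation on truth
  expect_lt(mean(reg$t0[reg$role == "wave1"]), mean(reg$t0[reg$role == "wave2"]))
  # ATAC opening precedes H3K27ac gain by lag_delta on truth
  expect_equal(mean(reg$t0[reg$role == "acetyl-gain"]) -
                 mean(reg$t0[reg$role == "opening"]),
               ds$truth$config$lag_delta, tolerance = 1e-12)
})

test_that("same config and seed give byte-identical fragment files", {
  cfg <- small_config()
  f1 <- tempfile(); f2 <- tempfile()
  write_fragments(generate_dataset(cfg)$fragments$H3K27ac, f1)
  write_fragments(generate_dataset(cfg)$fragments$H3K27ac, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("frip_target = 1 puts every fragment inside a truth region", {
  cfg <- synthetic_config(n_cell_types = 2, n_static_cells_per_type = 20,
                          n_trajectory_cells = 0, n_background_barcodes = 0,
                          frip_target = 1, depth_log_mean = log(100), seed = 3)
  ds <- generate_dataset(cfg)
  fr <- empirical_frip(ds$fragments$ATAC, ds$truth$regions)
  expect_true(all(fr == 1))
})

test_that("empirical FrIP matches frip_target within 3 binomial SDs", {
  cfg <- synthetic_config(n_cell_types = 2, n_static_cells_per_type = 120,
                          n_trajectory_cells = 0, n_background_barcodes = 0,
                          frip_target = 0.5, depth_log_mean = log(200), seed = 8)
  ds <- generate_dataset(cfg)
  fr <- ds$fragments$ATAC
  gr <- GenomicRanges::reduce(df_to_granges(
    unique(ds$truth$regions[c("chrom", "start", "end")])))
  hit <- IRanges::overlapsAny(df_to_granges(fr), gr)
  n <- length(hit)
  expect_lt(abs(mean(hit) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("expected_rate reflects the logistic programs", {
  ds <- small_dataset()
  truth <- ds$truth
  reg <- truth$regions[truth$regions$role == "opening", ][1, ]
  tr_cells <- truth$cells[truth$cells$class == "trajectory", ]
  early <- tr_cells$cell[which.min(tr_cells$t)]
  late <- tr_cells$cell[which.max(tr_cells$t)]
  expect_lt(truth$expected_rate(early, reg$region_id, "ATAC"),
            truth$expected_rate(late, reg$region_id, "ATAC"))
  bg <- truth$cells$cell[truth$cells$class == "background"][1]
  expect_equal(truth$expected_rate(bg, reg$region_id, "ATAC"), 0)
})

test_that("pseudobulk signal recovers the planted ATAC-to-H3K27ac lag", {
  ds <- small_dataset()
  cfg <- ds$truth$config
  reg <- ds$truth$regions
  tr <- cells_of(ds, "trajectory")
  tt <- latent_time(ds, tr)
  # half-rise midpoint of the per-cell in-region signal fraction over t
  mid_of <- function(fragments, r) {
    keep <- fragments$cell %in% tr
    fragments <- fragments[keep, ]
    gr <- GenomicRanges::reduce(df_to_granges(r[c("chrom", "start", "end")]))
    hit <- IRanges::overlapsAny(df_to_granges(fragments), gr)
    fcell <- factor(fragments$cell, levels = tr)
    y <- as.numeric(tapply(hit, fcell, sum))
    y[is.na(y)] <- 0
    tot <- as.numeric(table(fcell))
    y <- y / pmax(tot, 1)
    lf <- loess_fit(tt, y, span = 0.5)
    half <- (max(lf$fit) + min(lf$fit)) / 2
    lf$t[which(lf$fit >= half)[1]]
  }
  m_atac <- mid_of(ds$fragments$ATAC, reg[reg$role == "opening", ])
  m_ac <- mid_of(ds$fragments$H3K27ac, reg[reg$role == "acetyl-gain", ])
  expect_lt(abs((m_ac - m_atac) - cfg$lag_delta), 0.05)
})

test_that("emit_fastq injects duplicates and barcode mismatches as configured", {
  ds <- small_dataset()
  n_frag <- sum(vapply(ds$fragments, nrow, integer(1)))
  td <- withr::local_tempdir()
  em0 <- emit_fastq(ds, file.path(td, "nodup"), duplicate_rate = 0,
                    mismatch_inject_rate = 0)
  expect_identical(em0$n_reads, n_frag)
  wl <- ds$truth$barcode_map
  r1 <- read_fastq(em0$paths["R1"])
  expect_true(all(substr(r1$seq, 1, 8) %in% wl))
  em <- emit_fastq(ds, file.path(td, "dup"), duplicate_rate = 0.1,
                   mismatch_inject_rate = 0.05)
  expect_identical(em$n_reads, n_frag + as.integer(round(0.1 * n_frag)))
  expect_gt(nrow(em$injected_mismatches), 0)
  expect_true(all(em$injected_mismatches$barcode_true !=
                    em$injected_mismatches$barcode_observed))
  expect_error(emit_fastq(ds, td, barcode_map = wl[1:2]), "lacks modality")
})

test_that("fixture_align round-trips the emitted fragments", {
  ds <- small_dataset()
  td <- withr::local_tempdir()
  em <- emit_fastq(ds, td, duplicate_rate = 0, mismatch_inject_rate = 0)
  al <- fixture_align(em$paths["R1"], em$paths["I2"])
  all_fr <- do.call(rbind, ds$fragments)
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$cell))
  expect_identical(key(al), key(all_fr))
  expect_identical(attr(al, "n_skipped"), 0L)
  # corrupted read name is skipped with one counted warning
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@MMCT:1:chr1:100:200:AAAA:ATAC", "ACGT", "+", "IIII",
               "@garbage", "ACGT", "+", "IIII"), bad)
  expect_warning(al2 <- fixture_align(bad), "skipped 1")
  expect_identical(nrow(al2), 1L)
  expect_identical(attr(al2, "n_skipped"), 1L)
  # empty input
  empty <- tempfile(fileext = ".fastq"); file.create(empty)
  expect_identical(nrow(fixture_align(empty)), 0L)
})

test_that("fragment totals are conserved across classes and modalities", {
  ds <- small_dataset()
  cells <- ds$truth$cells
  for (m in names(ds$fragments)) {
    fr <- ds$fragments[[m]]
    expect_true(all(fr$cell %in% cells$cell))
    expect_true(all(fr$start < fr$end))
  }
})
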