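wl3 <- barcode_whitelist(c(ATAC = "AACCGGTT", H3K27ac = "CCGGTTAA",
                           H3K27me3 = "GGTTAACC"))

test_that("whitelist validation flags ambiguity-prone designs", {
  expect_warning(barcode_whitelist(c(a = "AAAA", b = "AAAT")), "Hamming")
  expect_error(barcode_whitelist(c(a = "AAAA", b = "AAA")), "equal length")
  expect_error(barcode_whitelist(c(a = "AANA", b = "CCCC")), "A/C/G/T")
  expect_error(barcode_whitelist(c("AAAA", "CCCC")), "named")
})

test_that("modality assignment follows the 1-mismatch correction rule", {
  # exact match
  expect_identical(as.character(assign_modality("AACCGGTT", wl3)), "ATAC")
  # one substitution from a unique entry
  expect_identical(as.character(assign_modality("TACCGGTT", wl3)), "ATAC")
  # beyond max_mismatch
  expect_identical(as.character(assign_modality("TTCCGGAA", wl3)), NA_character_)
  # equidistant tie at d = 1 between two entries
  wl_close <- suppressWarnings(barcode_whitelist(c(x = "AAAA", y = "AATT")))
  expect_identical(as.character(assign_modality("AAAT", wl_close)), NA_character_)
  # wrong length -> unassigned with counted warning
  expect_warning(lab <- assign_modality(c("AAA", "AACCGGTT"), wl3), "length")
  expect_identical(as.character(lab), c(NA, "ATAC"))
})

test_that("assignment equals the brute-force nearest-neighbor Hamming oracle", {
  set.seed(11)
  seqs <- random_dna(500, 8)
  got <- assign_modality(seqs, wl3)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  want <- vapply(seqs, function(s) {
    d <- vapply(wl3$entries, ham, numeric(1), a = s)
    dm <- min(d)
    if (dm > wl3$max_mismatch || sum(d == dm) > 1) NA_character_
    else names(wl3$entries)[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
  expect_identical(as.character(got), want)
})

test_that("reads with <= 1 substitution are always correctly assigned", {
  set.seed(12)
  truth <- sample(names(wl3$entries), 400, replace = TRUE)
  seqs <- unname(wl3$entries[truth])
  mut <- seq_len(200)
  seqs[mut] <- inject_substitutions(seqs[mut], 1)
  expect_identical(as.character(assign_modality(seqs, wl3)), truth)
})

test_that("demultiplex conserves reads and reports stats", {
  set.seed(13)
  truth <- sample(names(wl3$entries), 300, replace = TRUE)
  bc <- unname(wl3$entries[truth])
  bc[1:50] <- inject_substitutions(bc[1:50], 1)
  bc[51:60] <- strrep("N", 8)     # unassignable
  reads <- data.frame(seq = paste0(bc, random_dna(300, 28)), id = seq_len(300))
  dm <- demultiplex(reads, wl3)
  expect_identical(sum(dm$stats$per_modality) + dm$stats$unassigned, 300L)
  expect_identical(dm$stats$unassigned, 10L)
  got <- rep(NA_character_, 300)
  for (m in names(dm$assigned)) got[dm$assigned[[m]]$id] <- m
  expect_identical(got[-(51:60)], truth[-(51:60)])
  # truncated read shorter than the barcode
  short <- demultiplex(data.frame(seq = c("ACG", paste0(wl3$entries[1], "A"))), wl3)
  expect_identical(short$stats$unassigned, 1L)
})

test_that("assemble_fragments rejects malformed records and honors the shift flag", {
  rec <- data.frame(chrom = "chr1", start = c(0L, 100L, 50L),
                    end = c(100L, 100L, 250L), cell = "AC",
                    modality = "ATAC", stringsAsFactors = FALSE)
  out <- assemble_fragments(rec)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_rejected"), 1L)
  expect_identical(out$start, c(0L, 50L))      # default: no Tn5 shift
  shifted <- assemble_fragments(rec, shift_tn5 = TRUE)
  expect_identical(shifted$start, c(4L, 54L))
  expect_identical(shifted$end, c(95L, 245L))
  # barcode resolution path
  rec2 <- data.frame(chrom = "chr1", start = 0L, end = 10L, cell = "AC",
                     barcode = "TACCGGTT")
  expect_identical(assemble_fragments(rec2, wl3)$modality, "ATAC")
})

test_that("deduplication is exact and idempotent", {
  f <- data.frame(chrom = "chr1", start = c(1L, 1L), end = c(5L, 5L),
                  cell = "A", modality = "ATAC", count = 1L)
  d <- deduplicate(f)
  expect_identical(nrow(d$fragments), 1L)
  expect_equal(d$duplicate_rate, 0.5)
  expect_identical(d$multiplicity, 2L)
  distinct <- random_fragments(50)
  distinct <- distinct[!duplicated(distinct[1:4]), ]
  expect_equal(deduplicate(distinct)$duplicate_rate, 0)
  # planted d duplicates among n total
  set.seed(4)
  base <- random_fragments(40)
  base <- base[!duplicated(base[1:4]), ]
  d_n <- 7
  planted <- rbind(base, base[sample(nrow(base), d_n, replace = FALSE), ])
  dd <- deduplicate(planted)
  expect_equal(dd$duplicate_rate, d_n / nrow(planted))
  dd2 <- deduplicate(dd$fragments)
  expect_equal(dd2$duplicate_rate, 0)
  expect_identical(dd2$fragments[1:5], dd$fragments[1:5])
})

test_that("fragments files round-trip, sorted, with gzip support", {
  fr <- random_fragments(100)
  fr <- fr[!duplicated(fr[1:4]), ]
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_fragments(fr, path)
    back <- read_fragments(path, modality = "ATAC")
    expect_true(attr(back, "sorted"))
    ord <- order(fr$chrom, fr$start, fr$end, fr$cell)
    expect_identical(back[c("chrom", "start", "end", "cell", "count")],
                     data.frame(fr[ord, c("chrom", "start", "end", "cell", "count")],
                                row.names = NULL))
  }
  # empty collection -> header-less empty file
  p <- tempfile()
  write_fragments(fr[0, ], p)
  expect_identical(file.size(p), 0)
  expect_identical(nrow(read_fragments(p)), 0L)
  # malformed line -> error with line number
  bad <- tempfile()
  writeLines(c("chr1\t0\t10\tAC\t1", "chr1\t5\t20"), bad)
  expect_error(read_fragments(bad), "line 2")
})

test_that("demultiplexing synthetic reads with no injected errors is perfect", {
  ds <- small_dataset()
  td <- withr::local_tempdir()
  em <- emit_fastq(ds, td, duplicate_rate = 0, mismatch_inject_rate = 0)
  wl <- barcode_whitelist(ds$truth$barcode_map)
  dm <- demultiplex(em$paths["R1"], wl)
  expect_identical(dm$stats$unassigned, 0L)
  for (m in names(dm$assigned)) {
    expect_true(all(grepl(paste0(":", m, "$"), dm$assigned[[m]]$name)))
  }
  counts_truth <- table(em$reads$modality)
  expect_identical(as.integer(counts_truth[names(dm$stats$per_modality)]),
                   unname(dm$stats$per_modality))
})
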