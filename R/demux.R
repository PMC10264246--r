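#' Modality barcode whitelist
#'
#' Maps Tn5 barcode sequences to modality labels. Correction of up to
#' `max_mismatch` substitutions is unambiguous only when every pair of
#' entries is at Hamming distance >= 2*max_mismatch + 1; a violation gives a
#' warning (assignment still works, ambiguous reads are dropped).
#'
#' @param barcodes named character vector: names are modality labels, values
#'   equal-length barcode sequences over A/C/G/T.
#' @param max_mismatch maximum substitutions tolerated per barcode (default 1,
#'   matching standard debarcoding practice).
#' @return a `BarcodeWhitelist` object.
#' @export
barcode_whitelist <- function(barcodes, max_mismatch = 1) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    stopf("barcodes must be named by modality")
  L <- unique(nchar(barcodes))
  if (length(L) != 1) stopf("whitelist barcodes must have equal length")
  if (any(grepl("[^ACGT]", barcodes))) stopf("barcodes must be over A/C/G/T")
  if (anyDuplicated(barcodes)) stopf("duplicate barcode sequences")
  if (length(barcodes) > 1) {
    dmin <- min(utils::combn(seq_along(barcodes), 2, function(ij) {
      sum(strsplit(barcodes[ij[1]], "")[[1]] != strsplit(barcodes[ij[2]], "")[[1]])
    }))
    if (dmin < 2 * max_mismatch + 1)
      warnf("whitelist pairwise Hamming distance %d < %d; correction may be ambiguous",
            dmin, 2 * max_mismatch + 1)
  }
  structure(list(entries = barcodes, max_mismatch = as.integer(max_mismatch),
                 barcode_length = L), class = "BarcodeWhitelist")
}

#' Assign barcode sequences to modalities with mismatch tolerance
#'
#' Returns the modality of the unique whitelist entry within Hamming distance
#' <= `max_mismatch` of each sequence; sequences at distance >
#' `max_mismatch`, tied between two entries at the minimal distance, or of
#' the wrong length are unassigned (`NA`).
#'
#' @param seqs character vector of observed barcode sequences.
#' @param whitelist a [barcode_whitelist()].
#' @return character vector of modality labels (`NA` = unassigned) with the
#'   minimal Hamming distance in `attr(, "distance")`.
#' @export
assign_modality <- function(seqs, whitelist) {
  stopifnot(inherits(whitelist, "BarcodeWhitelist"))
  n <- length(seqs)
  out <- rep(NA_character_, n)
  dmin_all <- rep(NA_integer_, n)
  ok <- !is.na(seqs) & nchar(seqs) == whitelist$barcode_length
  n_bad <- sum(!ok)
  if (n_bad) warnf("%d sequence(s) with wrong barcode length left unassigned", n_bad)
  if (any(ok)) {
    D <- vapply(whitelist$entries, function(b) hamming_to(seqs[ok], b),
                numeric(sum(ok)))
    D <- matrix(D, nrow = sum(ok))
    dmin <- apply(D, 1, min)
    nmin <- rowSums(D == dmin)
    hit <- apply(D, 1, which.min)
    lab <- names(whitelist$entries)[hit]
    lab[dmin > whitelist$max_mismatch | nmin > 1] <- NA_character_
    out[ok] <- lab
    dmin_all[ok] <- as.integer(dmin)
  }
  attr(out, "distance") <- dmin_all
  out
}

#' Demultiplex barcoded reads into per-modality streams
#'
#' Reads carry the modality barcode as the 5' prefix of R1 (configurable
#' offset). Each read is routed via [assign_modality()]; ambiguous or
#' unmatched reads are dropped rather than guessed, since cross-modality
#' contamination is worse than read loss.
#'
#' @param reads data.frame with a `seq` column (R1 sequence) and any other
#'   per-read columns, or a FASTQ path.
#' @param whitelist a [barcode_whitelist()].
#' @param barcode_offset 0-based offset of the barcode within the read.
#' @return list with `assigned` (named list of per-modality data.frames, each
#'   gaining a `modality` column) and `stats` (a `DemuxStats` list:
#'   per-modality counts, unassigned/ambiguous counts, mismatch-distance
#'   histogram).
#' @export
demultiplex <- function(reads, whitelist, barcode_offset = 0) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (!"seq" %in% names(reads)) stopf("reads must have a 'seq' column")
  bl <- whitelist$barcode_length
  bc <- substr(reads$seq, barcode_offset + 1, barcode_offset + bl)
  bc[nchar(bc) < bl] <- NA_character_  # truncated reads -> unassigned
  lab <- suppressWarnings(assign_modality(bc, whitelist))
  d <- attr(lab, "distance")
  n <- nrow(reads)
  ambiguous <- sum(!is.na(d) & d <= whitelist$max_mismatch & is.na(lab))
  assigned <- lapply(setNames(nm = names(whitelist$entries)), function(m) {
    out <- reads[!is.na(lab) & lab == m, , drop = FALSE]
    out$modality <- rep(m, nrow(out))
    rownames(out) <- NULL
    out
  })
  hist <- table(factor(d[!is.na(lab)], levels = 0:whitelist$max_mismatch))
  stats <- structure(list(
    total = n,
    per_modality = vapply(assigned, nrow, integer(1)),
    unassigned = sum(is.na(lab)),
    ambiguous = ambiguous,
    mismatch_histogram = as.integer(hist)
  ), class = "DemuxStats")
  stopifnot(sum(stats$per_modality) + stats$unassigned == n)
  list(assigned = assigned, stats = stats)
}

#' Assemble fragments from aligned coordinate records
#'
#' @param records data.frame with chrom/start/end/cell and either a
#'   `modality` label or a `barcode` column to resolve against `whitelist`.
#' @param whitelist optional [barcode_whitelist()] used when records carry raw
#'   barcodes.
#' @param shift_tn5 apply the +4/-5 Tn5 insertion-site shift (off by
#'   default).
#' @return fragment data.frame; records with start >= end (or unassignable
#'   barcodes) are rejected, with counts in `attr(, "n_rejected")`.
#' @export
assemble_fragments <- function(records, whitelist = NULL, shift_tn5 = FALSE) {
  if (!"modality" %in% names(records)) {
    if (is.null(whitelist) || !"barcode" %in% names(records))
      stopf("records need a 'modality' column or a 'barcode' column plus whitelist")
    records$modality <- suppressWarnings(assign_modality(records$barcode, whitelist))
  }
  bad <- records$start >= records$end | is.na(records$modality)
  out <- records[!bad, c("chrom", "start", "end", "cell", "modality"), drop = FALSE]
  if (shift_tn5) {
    out$start <- out$start + 4L
    out$end <- out$end - 5L
    keep <- out$start < out$end
    bad[!bad][!keep] <- TRUE
    out <- out[keep, , drop = FALSE]
  }
  out$count <- 1L
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Collapse duplicate fragments
#'
#' Duplicates are exact copies on the key (chrom, start, end, cell,
#' modality), as produced by linear amplification. Surviving fragments carry
#' `count = 1`; occurrence multiplicity is reported separately.
#'
#' @param fragments fragment data.frame.
#' @return list with `fragments` (unique), `duplicate_rate`
#'   (duplicates/total) and `multiplicity` (per surviving fragment).
#' @export
deduplicate <- function(fragments) {
  n <- nrow(fragments)
  if (!n) return(list(fragments = fragments, duplicate_rate = 0,
                      multiplicity = integer(0)))
  key <- paste(fragments$chrom, fragments$start, fragments$end,
               fragments$cell, fragments$modality, sep = "\r")
  keep <- !duplicated(key)
  out <- fragments[keep, , drop = FALSE]
  out$count <- 1L
  rownames(out) <- NULL
  mult <- as.integer(table(key)[key[keep]])
  list(fragments = out, duplicate_rate = sum(!keep) / n, multiplicity = mult)
}

#' Write / read a 10x-style fragments file
#'
#' Tab-separated (chrom, start, end, cell barcode, count), 0-based half-open,
#' sorted by (chrom, start); `.gz` paths are compressed. One file holds one
#' modality; use [split()] + `write_fragments()` per modality for multimodal
#' sets.
#'
#' @param fragments fragment data.frame.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  ord <- order(fragments$chrom, fragments$start, fragments$end, fragments$cell)
  out <- fragments[ord, c("chrom", "start", "end", "cell", "count"), drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(out)) {
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fragments
#' @param modality modality label attached to the read fragments.
#' @export
read_fragments <- function(path, modality = NA_character_) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      cell = character(), count = integer())
    out$modality <- character(0)
    attr(out, "sorted") <- TRUE
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5)) stopf("malformed fragments line %d (expected 5 fields, got %d)",
                          which(nf != 5)[1], nf[nf != 5][1])
  m <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
  out <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), cell = m[, 4],
                    count = as.integer(m[, 5]), stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stopf("malformed fragments line %d (non-integer coordinates)",
          which(is.na(out$start) | is.na(out$end))[1])
  out$modality <- modality
  ord <- order(out$chrom, out$start)
  attr(out, "sorted") <- identical(ord, seq_len(nrow(out)))
  out
}
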