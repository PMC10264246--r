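#' @importFrom methods is
#' @importFrom stats rpois runif rnorm rlnorm plogis ppois p.adjust quantile
#'   median cor prcomp kmeans loess predict setNames aggregate dist sd var
#'   pnorm pwilcox complete.cases
#' @importFrom utils head read.table write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a fragment table
#'
#' Fragments are plain data frames in BED-style 0-based half-open coordinates
#' with columns `chrom`, `start`, `end`, `cell`, `modality` and `count`.
#'
#' @param fragments data.frame of fragments.
#' @param genome optional named vector of chromosome lengths; when given,
#'   chromosome names and bounds are checked.
#' @return the validated data.frame, invisibly coerced to canonical types.
#' @export
validate_fragments <- function(fragments, genome = NULL) {
  need <- c("chrom", "start", "end", "cell")
  miss <- setdiff(need, names(fragments))
  if (length(miss)) stopf("fragment table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"count" %in% names(fragments)) fragments$count <- 1L
  if (!"modality" %in% names(fragments)) fragments$modality <- NA_character_
  bad <- fragments$start >= fragments$end
  if (any(bad)) stopf("%d fragment(s) with start >= end", sum(bad))
  if (!is.null(genome)) {
    unk <- setdiff(unique(as.character(fragments$chrom)), names(genome))
    if (length(unk)) stopf("unknown chromosome(s): %s", paste(unk, collapse = ", "))
    over <- fragments$end > genome[as.character(fragments$chrom)]
    if (any(over)) stopf("%d fragment(s) exceed chromosome bounds", sum(over))
  }
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)
  fragments
}

#' Convert fragments or a region table to GRanges
#'
#' Interval tables throughout the package are 0-based half-open; GRanges is
#' 1-based closed, so `start + 1` is applied here (and undone by
#' [granges_to_df()]).
#'
#' @param x data.frame with `chrom`, `start`, `end` columns.
#' @param genome optional named vector of chromosome lengths (sets seqlengths).
#' @return a `GRanges` object; all other columns are kept as metadata.
#' @export
df_to_granges <- function(x, genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  meta <- x[setdiff(names(x), c("chrom", "start", "end"))]
  if (ncol(meta)) S4Vectors::mcols(gr) <- meta
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  gr
}

#' @rdname df_to_granges
#' @param gr a GRanges object.
#' @export
granges_to_df <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta)) out <- cbind(out, meta)
  rownames(out) <- NULL
  out
}

# Hamming distance between equal-length barcode strings, vectorised over seqs.
hamming_to <- function(seqs, ref) {
  L <- nchar(ref)
  refc <- strsplit(ref, "")[[1]]
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = L)
  colSums(m != refc)
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param len sequence length.
#' @return character vector of uniform-random A/C/G/T strings.
#' @export
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = len)
  do.call(paste0, split(m, row(m)))
}

#' Inject random base substitutions into barcode sequences
#'
#' Used to emulate sequencing errors in the modality barcode. Each selected
#' sequence receives `n_sub` substitutions at distinct positions, each to a
#' base different from the original.
#'
#' @param seqs character vector of equal-length sequences.
#' @param n_sub substitutions per sequence.
#' @param positions candidate positions (default: all).
#' @return character vector of mutated sequences.
#' @export
inject_substitutions <- function(seqs, n_sub = 1, positions = NULL) {
  if (!length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  if (is.null(positions)) positions <- seq_len(L)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    pos <- sample(positions, n_sub)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
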