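#' Broad peak calling parameters
#'
#' Defaults mirror the broad-call parameterization used for pseudobulk
#' CUT&Tag data: local background window 100 kb, broad q cutoff 0.1, minimum
#' peak length 1 kb, merge gap 1 kb, duplicates collapsed to one.
#'
#' @param bin_bp genome bin width used for counting.
#' @param local_lambda_bp centered window for the local Poisson background.
#' @param broad_cutoff BH q-value cutoff for significant bins.
#' @param min_length_bp minimum peak length.
#' @param max_gap_bp maximum gap merged between significant bins.
#' @param keep_dup fragment copies kept per duplicate key.
#' @return a `PeakCallParams` list.
#' @export
peak_params <- function(bin_bp = 200, local_lambda_bp = 1e5, broad_cutoff = 0.1,
                        min_length_bp = 1000, max_gap_bp = 1000, keep_dup = 1) {
  if (min_length_bp < bin_bp) stopf("min_length_bp must be >= bin_bp")
  if (broad_cutoff <= 0 || broad_cutoff >= 1) stopf("broad_cutoff must be in (0,1)")
  structure(as.list(environment()), class = "PeakCallParams")
}

genome_bins <- function(genome, bin_bp) {
  tiles <- GenomicRanges::tileGenome(setNames(as.integer(genome), names(genome)),
                                     tilewidth = bin_bp, cut.last.tile.in.chrom = TRUE)
  tiles
}

#' Call broad peaks from pooled fragments
#'
#' A deliberately simplified analog of a broad-domain caller: per-bin
#' fragment-overlap counts are tested against a Poisson background with
#' lambda equal to the larger of the genome-wide mean and a centered local
#' mean over `local_lambda_bp`; Benjamini-Hochberg q-values below
#' `broad_cutoff` define significant bins, which are merged across gaps up to
#' `max_gap_bp` and filtered to `min_length_bp`. No fragment-size model or
#' shifting is performed.
#'
#' @param fragments pooled (deduplicated) fragment data.frame.
#' @param genome named chromosome lengths.
#' @param params a [peak_params()] object.
#' @return a `PeakSet`: sorted, non-overlapping `GRanges` with a per-peak
#'   `score` (mean -log10 q over member bins).
#' @export
call_broad_peaks <- function(fragments, genome, params = peak_params()) {
  stopifnot(inherits(params, "PeakCallParams"))
  bins <- genome_bins(genome, params$bin_bp)
  empty <- GenomicRanges::GRanges()
  if (!nrow(fragments)) return(empty)
  if (params$keep_dup >= 1) fragments <- deduplicate(fragments)$fragments
  fr <- df_to_granges(fragments, genome)
  counts <- GenomicRanges::countOverlaps(bins, fr)
  lambda_global <- mean(counts)
  k <- max(1L, round(params$local_lambda_bp / params$bin_bp))
  if (k %% 2 == 0) k <- k + 1L
  chrom_f <- factor(as.character(GenomeInfoDb::seqnames(bins)),
                    levels = GenomeInfoDb::seqlevels(bins))
  local_mean <- unlist(lapply(split(counts, chrom_f), function(x) {
    if (length(x) < k) return(rep(mean(x), length(x)))
    lm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    lm[is.na(lm)] <- mean(x)
    lm
  }), use.names = FALSE)  # bins are already in seqlevels order
  lambda <- pmax(lambda_global, local_mean)
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- q < params$broad_cutoff
  if (!any(sig)) return(empty)
  merged <- GenomicRanges::reduce(bins[sig], min.gapwidth = params$max_gap_bp + 1L)
  merged <- merged[GenomicRanges::width(merged) >= params$min_length_bp]
  if (!length(merged)) return(empty)
  ov <- GenomicRanges::findOverlaps(bins[sig], merged)
  score <- tapply(-log10(pmax(q[sig][S4Vectors::queryHits(ov)], 1e-300)),
                  S4Vectors::subjectHits(ov), mean)
  merged$score <- as.numeric(score)
  GenomicRanges::sort(merged)
}

#' Overlap two peak sets
#'
#' A peak "overlaps" when it intersects at least 1 bp of any peak in the
#' other set; counts are reported from each set's perspective.
#'
#' @param a,b `GRanges` peak sets.
#' @return list with counts `a_only`, `b_only`, `a_overlapping`,
#'   `b_overlapping` and the corresponding fractions.
#' @export
overlap_peaksets <- function(a, b) {
  a_hit <- IRanges::overlapsAny(a, b)
  b_hit <- IRanges::overlapsAny(b, a)
  list(a_total = length(a), b_total = length(b),
       a_overlapping = sum(a_hit), b_overlapping = sum(b_hit),
       a_only = sum(!a_hit), b_only = sum(!b_hit),
       a_fraction = if (length(a)) mean(a_hit) else NA_real_,
       b_fraction = if (length(b)) mean(b_hit) else NA_real_)
}

#' Downsample fragments to a fixed total
#'
#' Uniform sampling without replacement (the standard depth-matching step
#' before comparing replicates); deterministic given `seed`.
#'
#' @param fragments fragment data.frame.
#' @param target_total fragments to keep.
#' @param seed integer seed.
#' @return fragment data.frame with exactly `target_total` rows.
#' @export
downsample_fragments <- function(fragments, target_total, seed = 1L) {
  n <- nrow(fragments)
  if (target_total > n) stopf("target_total (%d) exceeds fragment count (%d)",
                              target_total, n)
  if (target_total == n) return(fragments)
  with_seed(seed, {
    keep <- sort(sample.int(n, target_total))
    out <- fragments[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
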