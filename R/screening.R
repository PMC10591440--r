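# Candidate screening: depth/breadth filtering of classifier reports,
# unique k-mer accounting, read-length filtering, adapter trimming.

#' Candidate filter configuration
#'
#' Defaults follow the empirically determined screening thresholds for
#' ancient metagenomic libraries: at least 1000 unique k-mers (breadth of
#' coverage proxy) and at least 200 reads assigned directly to the taxon
#' (depth of coverage). Both comparisons are inclusive. Only rows whose
#' rank is in `rank_keep` are considered; some classifier taxonomies place
#' assemblies at `sequence` or `no rank`, so the set is configurable.
#'
#' @param min_unique_kmers minimum unique k-mer count (breadth proxy).
#' @param min_tax_reads minimum reads assigned directly to the taxon.
#' @param rank_keep character vector of rank labels to keep.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_unique_kmers = 1000, min_tax_reads = 200,
                          rank_keep = "species") {
  if (min_unique_kmers < 0 || min_tax_reads < 0)
    stop("thresholds must be >= 0")
  structure(list(min_unique_kmers = min_unique_kmers,
                 min_tax_reads = min_tax_reads,
                 rank_keep = rank_keep),
            class = "filter_config")
}

#' Filter classifier report rows by depth and breadth of coverage
#'
#' Keeps rows whose rank is in `config$rank_keep`, with
#' `taxReads >= min_tax_reads` (depth) and
#' `kmers >= min_unique_kmers` (breadth proxy). Row order is preserved.
#' Depth alone is not a reliable detection criterion: misassigned reads
#' stack at conserved regions, giving high depth but low breadth, which
#' the unique k-mer threshold rejects.
#'
#' @param rows report data.frame (see [read_krakenuniq_report()]).
#' @param config a [filter_config()].
#' @return the surviving rows.
#' @export
filter_candidates <- function(rows, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  keep <- rows$rank %in% config$rank_keep &
    rows$taxReads >= config$min_tax_reads &
    rows$kmers >= config$min_unique_kmers
  rows[keep, , drop = FALSE]
}

#' Number of k-mers per read
#'
#' A read of length `L` contains `L - k + 1` k-mers of length `k`. For a
#' typical 50 bp ancient DNA fragment and `k = 31` this gives 20 k-mers,
#' so 50 non-overlapping such reads can cover at most 50 x 20 = 1000
#' unique k-mers - the arithmetic behind the default breadth threshold.
#'
#' @param L read length in bp.
#' @param k k-mer length (default 31, the classifier database k-mer size).
#' @return integer count `L - k + 1`.
#' @export
kmers_per_read <- function(L, k = 31L) {
  if (any(k > L)) stop("k must not exceed the read length L")
  if (any(k < 1)) stop("k must be >= 1")
  as.integer(L - k + 1L)
}

#' Count distinct reference k-mers covered by alignments
#'
#' Counts the number of distinct k-mer strings of the reference whose
#' window is fully contained in at least one aligned read span. This is
#' the alignment-level quantity that the classifier's unique k-mer count
#' approximates as a breadth-of-coverage proxy.
#'
#' @param alignments an `alignment_set` data.frame (gapless; span length
#'   is `nchar(seq)`).
#' @param reference reference nucleotide sequence (single string).
#' @param k k-mer length.
#' @return integer count of distinct covered reference k-mers.
#' @export
count_unique_kmers_covered <- function(alignments, reference, k = 31L) {
  ref_len <- nchar(reference)
  if (nrow(alignments) == 0) return(0L)
  lens <- nchar(alignments$seq)
  if (any(alignments$pos < 0 | alignments$pos + lens > ref_len))
    stop("alignment out of reference bounds")
  has_window <- lens >= k
  if (!any(has_window)) return(0L)
  # 1-based start positions of k-mer windows fully inside a read span
  starts <- IRanges::IRanges(start = alignments$pos[has_window] + 1L,
                             end = alignments$pos[has_window] +
                               lens[has_window] - k + 1L)
  starts <- IRanges::reduce(starts)
  s <- unlist(mapply(seq, IRanges::start(starts), IRanges::end(starts),
                     SIMPLIFY = FALSE), use.names = FALSE)
  length(unique(substring(reference, s, s + k - 1L)))
}

#' Filter reads by length
#'
#' Keeps reads strictly longer than `min_len`. Short reads lack taxonomic
#' specificity; the default keeps reads of length above 31 bp, matching
#' the classifier k-mer size.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (see
#'   [read_fastq()]).
#' @param min_len length threshold (strict: kept reads have
#'   `nchar(seq) > min_len`).
#' @return the surviving reads.
#' @export
filter_reads_by_length <- function(reads, min_len = 31L) {
  if (min_len < 0) stop("min_len must be >= 0")
  reads[nchar(reads$seq) > min_len, , drop = FALSE]
}

#' Trim a 3'-end adapter from reads
#'
#' Scans each read for an exact match of an adapter prefix of at least
#' `min_overlap` bases; among qualifying matches (where the adapter prefix
#' matches until the read end or in full), the rightmost-starting one is
#' removed together with everything after it. Qualities are trimmed in
#' lockstep. Matching is exact: error-tolerant trimming is out of scope.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`.
#' @param adapter adapter nucleotide sequence (non-empty).
#' @param min_overlap minimum adapter prefix length for a match.
#' @return reads with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 10L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  cut_at <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    hit <- 0L
    for (start in seq_len(n)) {
      m <- min(nchar(adapter), n - start + 1L)
      if (m < min_overlap) break
      if (substr(s, start, start + m - 1L) ==
          substr(adapter, 1L, m)) hit <- start
    }
    hit
  }, integer(1), USE.NAMES = FALSE)
  trim <- cut_at > 0L
  reads$seq[trim] <- substr(reads$seq[trim], 1L, cut_at[trim] - 1L)
  if (!is.null(reads$qual))
    reads$qual[trim] <- substr(reads$qual[trim], 1L, cut_at[trim] - 1L)
  reads
}
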