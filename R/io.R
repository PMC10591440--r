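# File formats: FASTQ, FASTA, SAM, KrakenUniq-style report tables.

#' Read a FASTQ file
#'
#' @param path FASTQ file (4-line records, Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  sr <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(id = names(sr),
             seq = as.character(sr),
             qual = as.character(S4Vectors::mcols(sr)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (`qual` filled
#'   with constant "I" if absent).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$qual)) strrep("I", nchar(reads$seq)) else
    reads$qual
  con <- file(path, "wb")  # binary: byte-stable newlines on any platform
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' The full header line (minus the `>`) is used as the sequence name:
#' reference names in this package are species names and may contain
#' spaces, so the usual truncation at the first whitespace would lose
#' them.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), trimws(names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

empty_alignments <- function() {
  structure(data.frame(read_id = character(0), ref_id = character(0),
                       pos = integer(0), strand = character(0),
                       seq = character(0), edit_distance = integer(0),
                       mapq = integer(0), md = character(0),
                       stringsAsFactors = FALSE),
            class = c("alignment_set", "data.frame"))
}

#' Read alignments from a SAM file
#'
#' Primary alignments are returned as an `alignment_set` data.frame with
#' one row per record: `read_id`, `ref_id`, `pos` (0-based leftmost
#' reference coordinate; SAM's 1-based POS is converted on input),
#' `strand`, `seq` (reference-forward orientation, as stored in SAM),
#' `edit_distance` (the `NM` tag), `mapq`, and `md` (the `MD` tag, `NA`
#' when absent). The `MD` tag is used downstream to recover mismatch
#' identities; without it, mismatch-based metrics need the reference
#' sequences.
#'
#' @param path SAM (or BAM) file with `@SQ` header lines.
#' @return an `alignment_set` data.frame.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  flt <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE,
                                isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"),
    tag = c("NM", "MD"), flag = flt)
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  md <- x$tag$MD
  if (is.null(md)) md <- rep(NA_character_, n)
  out <- data.frame(read_id = x$qname,
                    ref_id = as.character(x$rname),
                    pos = x$pos - 1L,
                    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
                    seq = as.character(x$seq),
                    edit_distance = nm,
                    mapq = x$mapq,
                    md = md,
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Write alignments to a SAM file
#'
#' Emits a minimal gapless SAM: `@SQ` header lines for the supplied
#' references, 1-based POS, all-`M` CIGAR, constant qualities, and `NM`
#' plus `MD` tags.
#'
#' @param alignments an `alignment_set` data.frame (see [read_sam()]).
#' @param genomes named character vector of reference sequences (used for
#'   `@SQ` lengths; must cover every `ref_id`).
#' @param path output file.
#' @export
write_sam <- function(alignments, genomes, path) {
  refs <- unique(alignments$ref_id)
  missing_g <- setdiff(refs, names(genomes))
  if (length(missing_g))
    stop("no genome for reference(s): ", paste(missing_g, collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genomes),
                   nchar(genomes)))
  lens <- nchar(alignments$seq)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                  alignments$read_id,
                  ifelse(alignments$strand == "-", 16L, 0L),
                  alignments$ref_id,
                  alignments$pos + 1L,
                  alignments$mapq,
                  lens,
                  alignments$seq,
                  strrep("I", lens),
                  alignments$edit_distance,
                  alignments$md)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

# --- KrakenUniq-style reports ------------------------------------------

krakenuniq_columns <- c("pct", "reads", "taxReads", "kmers", "dup", "cov",
                        "taxID", "rank", "taxName")

#' Read a KrakenUniq-style report
#'
#' Parses the 9-column tab-separated KrakenUniq report dialect: `%`,
#' `reads`, `taxReads`, `kmers`, `dup`, `cov`, `taxID`, `rank`, `taxName`.
#' Lines starting with `#` or `%` are treated as comments/header.
#' Indentation of `taxName` is preserved.
#'
#' @param path report file.
#' @return data.frame with columns `pct`, `reads`, `taxReads`, `kmers`,
#'   `dup`, `cov`, `taxID`, `rank`, `taxName`, in file order.
#' @export
read_krakenuniq_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "%") &
    nzchar(lines)
  rows <- which(keep)
  out <- data.frame(pct = numeric(0), reads = numeric(0),
                    taxReads = numeric(0), kmers = numeric(0),
                    dup = numeric(0), cov = numeric(0), taxID = integer(0),
                    rank = character(0), taxName = character(0),
                    stringsAsFactors = FALSE)
  if (!length(rows)) return(out)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop("malformed report line ", rows[bad[1]], ": expected 9 ",
         "tab-separated fields, got ", lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  data.frame(pct = as.numeric(m[, 1]),
             reads = as.numeric(m[, 2]),
             taxReads = as.numeric(m[, 3]),
             kmers = as.numeric(m[, 4]),
             dup = as.numeric(m[, 5]),
             cov = as.numeric(m[, 6]),
             taxID = as.integer(m[, 7]),
             rank = m[, 8],
             taxName = m[, 9],
             stringsAsFactors = FALSE)
}

#' Write a KrakenUniq-style report
#'
#' Inverse of [read_krakenuniq_report()]; fields are written verbatim so a
#' read/write cycle round-trips byte-identically.
#'
#' @param rows data.frame in the layout returned by
#'   [read_krakenuniq_report()].
#' @param path output file.
#' @export
write_krakenuniq_report <- function(rows, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(c("%", "reads", "taxReads", "kmers", "dup", "cov",
                       "taxID", "rank", "taxName"), collapse = "\t"),
               sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                       format_num(rows$pct), format_num(rows$reads),
                       format_num(rows$taxReads), format_num(rows$kmers),
                       format_num(rows$dup), format_num(rows$cov),
                       rows$taxID, rows$rank, rows$taxName)),
             con, sep = "\n")
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.6f", x)))
}

#' Write a candidate list (filtered report) as TSV
#'
#' @param rows filtered report rows (see [filter_candidates()]).
#' @param path output file.
#' @export
write_candidates <- function(rows, path) {
  out <- data.frame(taxID = rows$taxID,
                    taxName = trimws(rows$taxName),
                    taxReads = rows$taxReads,
                    kmers = rows$kmers)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               sprintf("%d\t%s\t%s\t%s", out$taxID, out$taxName,
                       format_num(out$taxReads), format_num(out$kmers))),
             con, sep = "\n")
  invisible(path)
}
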