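# Alignment-based validation and authentication metrics: coverage depth,
# breadth and binned evenness, deamination profiles, edit distances, read
# lengths, percent identity, PMD scores, assigned-read counts.

#' Mean depth of coverage
#'
#' Depth of coverage in X units: total aligned bases divided by the
#' reference length. Four reads of length L on a genome of length 4L give
#' 1X regardless of where they map - which is why depth alone cannot
#' separate even (true) from stacked (spurious) alignments.
#'
#' @param alignments an `alignment_set` data.frame.
#' @param ref_length reference length in bp (> 0).
#' @return mean depth (numeric).
#' @export
compute_depth <- function(alignments, ref_length) {
  if (ref_length <= 0) stop("ref_length must be > 0")
  sum(nchar(alignments$seq)) / ref_length
}

coverage_rle <- function(alignments, ref_length) {
  lens <- nchar(alignments$seq)
  if (nrow(alignments) &&
      any(alignments$pos < 0 | alignments$pos + lens > ref_length))
    stop("alignment out of reference bounds")
  IRanges::coverage(IRanges::IRanges(start = alignments$pos + 1L,
                                     width = lens),
                    width = ref_length)
}

#' Breadth of coverage
#'
#' Fraction of reference positions covered by at least one aligned read.
#' Four stacked reads of length L on a 4L genome give 25 percent; four
#' reads tiling it give 100 percent.
#'
#' @inheritParams compute_depth
#' @return fraction in `[0, 1]`.
#' @export
compute_breadth <- function(alignments, ref_length) {
  if (ref_length <= 0) stop("ref_length must be > 0")
  if (nrow(alignments) == 0) return(0)
  sum(coverage_rle(alignments, ref_length) > 0L) / ref_length
}

#' Binned evenness-of-coverage profile
#'
#' Splits the reference into `n_bins` equal bins (the last bin absorbs the
#' remainder) and computes the local breadth of coverage in each bin: the
#' number of positions covered by at least one read, divided by the bin
#' size. Genome-wide breadth equals the length-weighted mean of the bin
#' values. An evenly covered genome has few or no zero bins even at low
#' overall breadth.
#'
#' @inheritParams compute_depth
#' @param n_bins number of bins (default 100; `ref_length` must be at
#'   least `n_bins`).
#' @return an object of class `coverage_profile`: list with `depth_mean`,
#'   `breadth`, `bin_breadth` (length `n_bins`), `bin_sizes`, `ref_length`.
#' @export
compute_evenness_profile <- function(alignments, ref_length,
                                     n_bins = 100L) {
  if (ref_length < n_bins)
    stop("ref_length (", ref_length, ") is smaller than n_bins (", n_bins,
         "); use fewer bins")
  bin_size <- ref_length %/% n_bins
  bin_sizes <- rep.int(bin_size, n_bins)
  bin_sizes[n_bins] <- ref_length - bin_size * (n_bins - 1L)
  covered <- if (nrow(alignments) == 0) {
    logical(ref_length)
  } else {
    as.vector(coverage_rle(alignments, ref_length) > 0L)
  }
  bin_of <- rep.int(seq_len(n_bins), bin_sizes)
  hits <- vapply(split(covered, bin_of), sum, numeric(1))
  structure(list(depth_mean = compute_depth(alignments, ref_length),
                 breadth = sum(covered) / ref_length,
                 bin_breadth = unname(hits / bin_sizes),
                 bin_sizes = bin_sizes,
                 ref_length = ref_length),
            class = "coverage_profile")
}

# --- Mismatch recovery (MD-tag based) ----------------------------------

# Reconstruct reference characters of a gapless alignment from the stored
# read sequence and MD tag: matched positions carry the read base, MD
# letters carry the mismatched reference base. Indel-containing MD tags
# (with '^') are rejected; substitutions only.
parse_md_ref <- function(seq_ch, md) {
  if (is.na(md)) stop("MD tag required to recover mismatch identities")
  if (grepl("^", md, fixed = TRUE))
    stop("indel-containing alignments are not supported (MD: ", md, ")")
  ref <- seq_ch
  toks <- regmatches(md, gregexpr("[0-9]+|[A-Z]", md))[[1]]
  at <- 0L
  for (t in toks) {
    if (grepl("^[0-9]", t)) {
      at <- at + as.integer(t)
    } else {
      at <- at + 1L
      ref[at] <- t
    }
  }
  if (at != length(seq_ch))
    stop("MD tag length (", at, ") disagrees with sequence length (",
         length(seq_ch), ")")
  ref
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Flatten alignments into per-base oriented (read 5'->3') tables:
# read base, reference base, 1-based distance from the 5' and 3' read
# ends. Reverse-strand records are complemented and flipped.
oriented_bases <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0)
    return(data.frame(read = character(0), ref = character(0),
                      aln = integer(0), pos5 = integer(0),
                      pos3 = integer(0)))
  seq_ch <- strsplit(alignments$seq, "", fixed = TRUE)
  lens <- lengths(seq_ch)
  read_l <- vector("list", n)
  ref_l <- vector("list", n)
  for (i in seq_len(n)) {
    rd <- seq_ch[[i]]
    rf <- parse_md_ref(rd, alignments$md[i])
    if (alignments$strand[i] == "-") {
      rd <- rev(unname(comp_base[rd]))
      rf <- rev(unname(comp_base[rf]))
    }
    read_l[[i]] <- rd
    ref_l[[i]] <- rf
  }
  pos5 <- sequence(lens)
  data.frame(read = unlist(read_l, use.names = FALSE),
             ref = unlist(ref_l, use.names = FALSE),
             aln = rep.int(seq_len(n), lens),
             pos5 = pos5,
             pos3 = rep.int(lens, lens) - pos5 + 1L,
             stringsAsFactors = FALSE)
}

#' Deamination profile
#'
#' Per-position C-to-T mismatch frequency at 5' read positions and G-to-A
#' frequency at 3' positions (post-mortem deamination read on the
#' complementary strand), over a window of `P` positions from each end.
#' Reverse-strand alignments are complemented and flipped into read
#' orientation before tallying. Frequencies are `NA` where no informative
#' (reference C, respectively G) site was observed.
#'
#' @param alignments an `alignment_set` with `md` tags populated.
#' @param P window size in bp from each read end.
#' @return an object of class `deamination_profile`: list with `p5_ct`,
#'   `p3_ga` (length-`P` frequencies), `n5_informative`,
#'   `n3_informative` (site counts), and `P`.
#' @export
compute_deamination_profile <- function(alignments, P = 15L) {
  ob <- oriented_bases(alignments)
  tally <- function(pos, ref_base, read_base) {
    sel <- ob[ob[[pos]] <= P, , drop = FALSE]
    inf <- tabulate(sel[[pos]][sel$ref == ref_base], nbins = P)
    ev <- tabulate(sel[[pos]][sel$ref == ref_base & sel$read == read_base],
                   nbins = P)
    list(freq = ifelse(inf > 0, ev / inf, NA_real_), n = inf)
  }
  t5 <- tally("pos5", "C", "T")
  t3 <- tally("pos3", "G", "A")
  structure(list(p5_ct = t5$freq, p3_ga = t3$freq,
                 n5_informative = t5$n, n3_informative = t3$n,
                 P = as.integer(P)),
            class = "deamination_profile")
}

#' Classify reads as damaged
#'
#' A read is damaged when it carries at least one C-to-T mismatch within
#' the first `terminal_window` 5' positions or at least one G-to-A
#' mismatch within the last `terminal_window` 3' positions (strand
#' corrected). The window is a convention of damage-pattern tooling and is
#' exposed as a parameter.
#'
#' @param alignments an `alignment_set` with `md` tags populated.
#' @param terminal_window terminal window size in bp.
#' @return logical vector, one element per alignment row.
#' @export
is_damaged <- function(alignments, terminal_window = 5L) {
  ob <- oriented_bases(alignments)
  hit <- (ob$pos5 <= terminal_window & ob$ref == "C" & ob$read == "T") |
    (ob$pos3 <= terminal_window & ob$ref == "G" & ob$read == "A")
  out <- logical(nrow(alignments))
  out[unique(ob$aln[hit])] <- TRUE
  out
}

#' Edit-distance histograms (all and damaged reads)
#'
#' Counts of per-read edit distance (SAM `NM`) over bins 0 to 10, with
#' values of 10 or more pooled into the last bin; the second histogram is
#' restricted to damaged reads (see [is_damaged()]). True hits decay in
#' mismatch count, so most mass is expected at low edit distance.
#'
#' @param alignments an `alignment_set`.
#' @param damaged logical vector as from [is_damaged()]; computed from the
#'   alignments when `NULL`.
#' @param terminal_window passed to [is_damaged()] when `damaged` is NULL.
#' @return list with integer vectors `edit_all` and `edit_damaged`, both
#'   named "0" to "10".
#' @export
edit_distance_histograms <- function(alignments, damaged = NULL,
                                     terminal_window = 5L) {
  if (is.null(damaged)) damaged <- is_damaged(alignments, terminal_window)
  hist_of <- function(nm) {
    b <- pmin(nm, 10L)
    setNames(tabulate(b + 1L, nbins = 11L), as.character(0:10))
  }
  list(edit_all = hist_of(alignments$edit_distance),
       edit_damaged = hist_of(alignments$edit_distance[damaged]))
}

#' Per-read percent identity
#'
#' `100 * (aligned length - edit distance) / aligned length`.
#'
#' @param alignments an `alignment_set`.
#' @return numeric vector of percent identities.
#' @export
percent_identity <- function(alignments) {
  lens <- nchar(alignments$seq)
  if (any(lens == 0)) stop("aligned length must be > 0")
  100 * (lens - alignments$edit_distance) / lens
}

#' Percent-identity histogram
#'
#' Counts of reads per identity bin `[80,85)`, `[85,90)`, `[90,95)`,
#' `[95,100]`; reads below 80 percent identity are not counted.
#'
#' @param alignments an `alignment_set`.
#' @return named integer vector of four bin counts.
#' @export
identity_histogram <- function(alignments) {
  pid <- percent_identity(alignments)
  pid <- pid[pid >= 80 & pid <= 100]
  bin <- findInterval(pid, c(80, 85, 90, 95), rightmost.closed = FALSE)
  setNames(tabulate(bin, nbins = 4L),
           c("[80,85)", "[85,90)", "[90,95)", "[95,100]"))
}

#' Post-mortem damage model parameters for PMD scoring
#'
#' The per-site deamination probability decays exponentially with the
#' distance `z` from the relevant fragment end:
#' `D(z) = p_base + (p_max - p_base) * exp(-decay_rate * z)` (`z = 0` at
#' the terminal base). The null model attributes every mismatch to
#' sequencing error at rate `err`. Defaults mirror the simulator's Briggs
#' defaults so that parameter recovery is testable end to end; they are
#' not the constants of any external damage-scoring tool.
#'
#' @param decay_rate exponential decay rate per bp (> 0).
#' @param p_max terminal damage probability.
#' @param p_base background damage probability.
#' @param err sequencing error probability per base.
#' @return an object of class `pmd_params`.
#' @export
pmd_params <- function(decay_rate = 0.5, p_max = 0.3, p_base = 0.01,
                       err = 0.001) {
  if (decay_rate <= 0) stop("decay_rate must be > 0")
  if (p_base < 0 || p_max > 1 || p_base > p_max)
    stop("need 0 <= p_base <= p_max <= 1")
  structure(list(decay_rate = decay_rate, p_max = p_max, p_base = p_base,
                 err = err), class = "pmd_params")
}

#' Per-read PMD scores
#'
#' Log-likelihood ratio of the damage model versus the null model, summed
#' over informative sites of each read: reference-C sites scored against
#' the 5' end distance and reference-G sites against the 3' end distance.
#' At an informative site the damage model assigns probability `D(z)` to
#' the deaminated base (T at reference C, A at reference G) and `1 - D(z)`
#' to the retained base; the null model assigns `err` and `1 - err`.
#' Other sites contribute 0. Positive scores indicate likely ancient
#' reads.
#'
#' @param alignments an `alignment_set` with `md` tags populated.
#' @param params a [pmd_params()].
#' @return numeric vector of per-read scores.
#' @export
pmd_score <- function(alignments, params = pmd_params()) {
  ob <- oriented_bases(alignments)
  scores <- numeric(nrow(alignments))
  if (nrow(ob) == 0) return(scores)
  d_of <- function(z) params$p_base +
    (params$p_max - params$p_base) * exp(-params$decay_rate * z)
  site_score <- function(z, hit, kept) {
    D <- d_of(z)
    ifelse(hit, log(D / params$err),
           ifelse(kept, log((1 - D) / (1 - params$err)), 0))
  }
  c_sites <- ob$ref == "C"
  g_sites <- ob$ref == "G"
  contrib <- numeric(nrow(ob))
  contrib[c_sites] <- site_score(ob$pos5[c_sites] - 1L,
                                 ob$read[c_sites] == "T",
                                 ob$read[c_sites] == "C")
  contrib[g_sites] <- site_score(ob$pos3[g_sites] - 1L,
                                 ob$read[g_sites] == "A",
                                 ob$read[g_sites] == "G")
  agg <- rowsum(contrib, ob$aln)
  scores[as.integer(rownames(agg))] <- agg[, 1]
  scores
}

#' Count assigned reads per reference
#'
#' Per-reference primary-alignment counts with mapping quality strictly
#' above `min_mapq`; the default `min_mapq = 0` counts uniquely mapped
#' reads (MAPQ > 0).
#'
#' @param x an `alignment_set` or a path to a SAM/BAM file.
#' @param min_mapq strict lower bound on MAPQ.
#' @return named integer vector of counts per `ref_id`.
#' @export
count_assigned <- function(x, min_mapq = 0L) {
  aln <- if (is.character(x)) read_sam(x) else x
  keep <- aln$mapq > min_mapq
  tab <- table(aln$ref_id[keep])
  setNames(as.integer(tab), names(tab))
}

#' Compute the full authentication metrics bundle for one taxon
#'
#' Wraps the individual metric functions into the eight-summary bundle
#' consumed by the scoring system: deamination profile, coverage
#' (depth/breadth/evenness), edit-distance histograms for all and damaged
#' reads, read-length distribution, PMD scores, assigned-read count, and
#' percent identity / ANI.
#'
#' @param alignments an `alignment_set` for one taxon in one sample, with
#'   `md` populated.
#' @param ref_length reference genome length in bp.
#' @param n_bins evenness bins.
#' @param P deamination window.
#' @param terminal_window damaged-read terminal window.
#' @param pmd a [pmd_params()].
#' @return an object of class `auth_metrics`.
#' @export
compute_auth_metrics <- function(alignments, ref_length, n_bins = 100L,
                                 P = 15L, terminal_window = 5L,
                                 pmd = pmd_params()) {
  damaged <- is_damaged(alignments, terminal_window)
  eh <- edit_distance_histograms(alignments, damaged)
  auth_metrics(
    deamination = compute_deamination_profile(alignments, P),
    coverage = compute_evenness_profile(alignments, ref_length, n_bins),
    edit_all = eh$edit_all,
    edit_damaged = eh$edit_damaged,
    read_lengths = nchar(alignments$seq),
    pmd_scores = pmd_score(alignments, pmd),
    n_assigned = nrow(alignments),
    identity_hist = identity_histogram(alignments),
    ani_mean = if (nrow(alignments)) mean(percent_identity(alignments))
      else NA_real_)
}

#' Construct an authentication metrics bundle
#'
#' Container for the eight per-taxon per-sample summaries feeding the
#' authentication score. Usually produced by [compute_auth_metrics()];
#' the constructor is exported so bundles can be built from externally
#' computed summaries.
#'
#' @param deamination a `deamination_profile`.
#' @param coverage a `coverage_profile`.
#' @param edit_all,edit_damaged edit-distance count vectors named "0" to
#'   "10" (`edit_damaged` restricted to damaged reads).
#' @param read_lengths integer vector of per-read lengths.
#' @param pmd_scores numeric vector of per-read PMD scores.
#' @param n_assigned number of assigned reads.
#' @param identity_hist percent-identity bin counts.
#' @param ani_mean mean percent identity across assigned reads.
#' @return an object of class `auth_metrics`.
#' @export
auth_metrics <- function(deamination, coverage, edit_all, edit_damaged,
                         read_lengths, pmd_scores, n_assigned,
                         identity_hist, ani_mean) {
  structure(list(deamination = deamination, coverage = coverage,
                 edit_all = edit_all, edit_damaged = edit_damaged,
                 read_lengths = read_lengths,
                 read_length_median = median(read_lengths),
                 pmd_scores = pmd_scores,
                 n_assigned = n_assigned,
                 identity_hist = identity_hist,
                 ani_mean = ani_mean),
            class = "auth_metrics")
}

#' Serialize an authentication metrics bundle to a TSV file
#'
#' Writes one `metric<TAB>key<TAB>value` row per scalar summary so the
#' bundle can be inspected or re-read without R serialization.
#'
#' @param metrics an `auth_metrics` object.
#' @param path output file.
#' @export
write_auth_metrics <- function(metrics, path) {
  rows <- rbind(
    data.frame(metric = "deamination_p5_ct",
               key = seq_along(metrics$deamination$p5_ct),
               value = metrics$deamination$p5_ct),
    data.frame(metric = "deamination_p3_ga",
               key = seq_along(metrics$deamination$p3_ga),
               value = metrics$deamination$p3_ga),
    data.frame(metric = "deamination_n5",
               key = seq_along(metrics$deamination$n5_informative),
               value = metrics$deamination$n5_informative),
    data.frame(metric = "deamination_n3",
               key = seq_along(metrics$deamination$n3_informative),
               value = metrics$deamination$n3_informative),
    data.frame(metric = "bin_breadth",
               key = seq_along(metrics$coverage$bin_breadth),
               value = metrics$coverage$bin_breadth),
    data.frame(metric = "coverage", key = "depth_mean",
               value = metrics$coverage$depth_mean),
    data.frame(metric = "coverage", key = "breadth",
               value = metrics$coverage$breadth),
    data.frame(metric = "coverage", key = "ref_length",
               value = if (is.null(metrics$coverage$ref_length))
                 NA_real_ else metrics$coverage$ref_length),
    data.frame(metric = "edit_all", key = names(metrics$edit_all),
               value = as.numeric(metrics$edit_all)),
    data.frame(metric = "edit_damaged", key = names(metrics$edit_damaged),
               value = as.numeric(metrics$edit_damaged)),
    data.frame(metric = "read_length", key = "median",
               value = metrics$read_length_median),
    if (length(metrics$read_lengths))
      data.frame(metric = "read_length_value",
                 key = seq_along(metrics$read_lengths),
                 value = metrics$read_lengths),
    data.frame(metric = "pmd", key = "frac_gt3",
               value = if (length(metrics$pmd_scores))
                 mean(metrics$pmd_scores > 3) else NA_real_),
    if (length(metrics$pmd_scores))
      data.frame(metric = "pmd_score_value",
                 key = seq_along(metrics$pmd_scores),
                 value = metrics$pmd_scores),
    data.frame(metric = "n_assigned", key = "n",
               value = metrics$n_assigned),
    data.frame(metric = "identity", key = names(metrics$identity_hist),
               value = as.numeric(metrics$identity_hist)),
    data.frame(metric = "identity", key = "ani_mean",
               value = metrics$ani_mean))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("metric\tkey\tvalue",
               sprintf("%s\t%s\t%s", rows$metric, rows$key,
                       ifelse(is.na(rows$value), "NA",
                              format_num_full(rows$value)))),
             con, sep = "\n")
  invisible(path)
}

format_num_full <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read an authentication metrics bundle back from TSV
#'
#' Inverse of [write_auth_metrics()]: reconstructs an [auth_metrics()]
#' bundle sufficient for scoring and plotting from a serialized metrics
#' table.
#'
#' @param path metrics TSV written by [write_auth_metrics()].
#' @return an `auth_metrics` object.
#' @export
read_auth_metrics <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "numeric"),
                  na.strings = "NA")
  grab <- function(metric, key = NULL) {
    sel <- d$metric == metric
    if (!is.null(key)) sel <- sel & d$key == key
    v <- d$value[sel]
    if (!is.null(key)) v else v[order(as.integer(d$key[sel]))]
  }
  deam <- structure(list(p5_ct = grab("deamination_p5_ct"),
                         p3_ga = grab("deamination_p3_ga"),
                         n5_informative = grab("deamination_n5"),
                         n3_informative = grab("deamination_n3"),
                         P = length(grab("deamination_p5_ct"))),
                    class = "deamination_profile")
  bb <- grab("bin_breadth")
  cov <- structure(list(depth_mean = grab("coverage", "depth_mean"),
                        breadth = grab("coverage", "breadth"),
                        bin_breadth = bb,
                        bin_sizes = NULL,
                        ref_length = grab("coverage", "ref_length")),
                   class = "coverage_profile")
  ed_keys <- as.character(0:10)
  ed_all <- setNames(vapply(ed_keys, function(k) grab("edit_all", k),
                            numeric(1)), ed_keys)
  ed_dam <- setNames(vapply(ed_keys, function(k) grab("edit_damaged", k),
                            numeric(1)), ed_keys)
  id_keys <- c("[80,85)", "[85,90)", "[90,95)", "[95,100]")
  idh <- setNames(vapply(id_keys, function(k) grab("identity", k),
                         numeric(1)), id_keys)
  auth_metrics(deamination = deam, coverage = cov,
               edit_all = ed_all, edit_damaged = ed_dam,
               read_lengths = grab("read_length_value"),
               pmd_scores = grab("pmd_score_value"),
               n_assigned = grab("n_assigned", "n"),
               identity_hist = idh,
               ani_mean = grab("identity", "ani_mean"))
}
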