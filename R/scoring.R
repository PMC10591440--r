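# The 0-10 authentication score: eight validation/authentication metrics,
# each contributing its weight when its criterion passes.

#' Authentication score weights
#'
#' Points awarded per passing metric. Evenness of coverage carries +2 as
#' the decisive criterion of true microbial presence; the deamination
#' profile contributes up to +2 in total because the 5' and 3' ends count
#' independently (+1 each) as the decisive evidence of ancient origin.
#' Every other metric adds +1, so the total ranges from 0 to 10.
#'
#' @param deam5,deam3 terminal deamination at the 5' / 3' end.
#' @param evenness evenness of coverage.
#' @param edit_all,edit_damaged declining edit distance (all / damaged
#'   reads).
#' @param read_length short-fragment read length distribution.
#' @param pmd post-mortem damage score distribution.
#' @param n_reads number of assigned reads (depth of coverage).
#' @param identity average nucleotide identity.
#' @return an object of class `score_weights`.
#' @export
score_weights <- function(deam5 = 1, deam3 = 1, evenness = 2,
                          edit_all = 1, edit_damaged = 1, read_length = 1,
                          pmd = 1, n_reads = 1, identity = 1) {
  structure(list(deam5 = deam5, deam3 = deam3, evenness = evenness,
                 edit_all = edit_all, edit_damaged = edit_damaged,
                 read_length = read_length, pmd = pmd, n_reads = n_reads,
                 identity = identity),
            class = "score_weights")
}

#' Authentication score criteria
#'
#' Thresholds deciding whether each metric's points are awarded. Each
#' criterion is a pure predicate on an [auth_metrics()] bundle; missing
#' summaries fail their criterion. The defaults are this package's
#' interpretation of standard authentication practice:
#'
#' \itemize{
#'   \item deamination (per end): terminal mismatch frequency at least
#'     `deam_min_rate`, at least `deam_fold` times the interior baseline
#'     (positions `deam_interior`), with at least `deam_min_sites`
#'     informative terminal sites (guards against single-read artifacts);
#'   \item evenness: observed breadth at least `evenness_min_ratio` of the
#'     Lander-Waterman expectation `1 - exp(-depth)` (normalising breadth
#'     for depth), and at least `evenness_min_nonzero` of bins non-empty;
#'   \item edit distance: histogram mode at edit distance
#'     `edit_mode_max` or less and counts non-increasing over bins 0 to 3
#'     allowing `edit_max_inversions` inversion(s); the damaged-read
#'     version additionally requires `edit_damaged_min_reads` damaged
#'     reads as a statistical floor;
#'   \item read length: median at most `read_length_max_median` bp (the
#'     ancient DNA fragmentation signature);
#'   \item pmd: at least `pmd_min_frac` of reads with PMD score above
#'     `pmd_cut`;
#'   \item n_reads: at least `n_reads_min` assigned reads;
#'   \item identity: mean percent identity at least `ani_min`.
#' }
#'
#' @param deam_min_rate,deam_fold,deam_interior,deam_min_sites deamination
#'   thresholds (see above).
#' @param evenness_min_ratio,evenness_min_nonzero evenness thresholds.
#' @param edit_mode_max,edit_max_inversions,edit_damaged_min_reads
#'   edit-distance thresholds.
#' @param read_length_max_median median read length bound in bp.
#' @param pmd_cut,pmd_min_frac PMD thresholds.
#' @param n_reads_min assigned-read floor.
#' @param ani_min mean percent identity floor.
#' @return an object of class `score_criteria`.
#' @export
score_criteria <- function(deam_min_rate = 0.05, deam_fold = 2,
                           deam_interior = 8:12, deam_min_sites = 10,
                           evenness_min_ratio = 0.8,
                           evenness_min_nonzero = 0.4,
                           edit_mode_max = 1, edit_max_inversions = 1,
                           edit_damaged_min_reads = 20,
                           read_length_max_median = 100,
                           pmd_cut = 3, pmd_min_frac = 0.10,
                           n_reads_min = 200, ani_min = 90) {
  structure(list(deam_min_rate = deam_min_rate, deam_fold = deam_fold,
                 deam_interior = deam_interior,
                 deam_min_sites = deam_min_sites,
                 evenness_min_ratio = evenness_min_ratio,
                 evenness_min_nonzero = evenness_min_nonzero,
                 edit_mode_max = edit_mode_max,
                 edit_max_inversions = edit_max_inversions,
                 edit_damaged_min_reads = edit_damaged_min_reads,
                 read_length_max_median = read_length_max_median,
                 pmd_cut = pmd_cut, pmd_min_frac = pmd_min_frac,
                 n_reads_min = n_reads_min, ani_min = ani_min),
            class = "score_criteria")
}

pass_or_false <- function(x) isTRUE(x)

deam_pass <- function(freq, n_informative, criteria) {
  p1 <- freq[1]
  interior <- freq[criteria$deam_interior]
  base <- if (all(is.na(interior))) 0 else mean(interior, na.rm = TRUE)
  pass_or_false(!is.na(p1) &&
                  p1 >= criteria$deam_min_rate &&
                  p1 >= criteria$deam_fold * base &&
                  n_informative[1] >= criteria$deam_min_sites)
}

edit_decay_pass <- function(h, criteria) {
  if (is.null(h) || sum(h) == 0) return(FALSE)
  mode_ed <- as.integer(names(h)[which.max(h)])
  d <- diff(as.numeric(h[as.character(0:3)]))
  pass_or_false(mode_ed <= criteria$edit_mode_max &&
                  sum(d > 0) <= criteria$edit_max_inversions)
}

#' Score one taxon in one sample
#'
#' Evaluates each criterion on the metrics bundle and awards the
#' corresponding weight when it passes; the total is the sum of awarded
#' points, ranging from 0 (absent or modern contaminant) to 10 (present
#' and ancient) under default weights.
#'
#' @param metrics an [auth_metrics()] bundle.
#' @param criteria a [score_criteria()].
#' @param weights a [score_weights()].
#' @return an object of class `auth_score`: list with `components` (named
#'   vector of awarded points) and `total`.
#' @export
score_taxon <- function(metrics, criteria = score_criteria(),
                        weights = score_weights()) {
  stopifnot(inherits(metrics, "auth_metrics"))
  cov <- metrics$coverage
  even_pass <- pass_or_false(
    !is.null(cov) && cov$depth_mean > 0 &&
      cov$breadth / (1 - exp(-cov$depth_mean)) >=
        criteria$evenness_min_ratio &&
      mean(cov$bin_breadth > 0) >= criteria$evenness_min_nonzero)
  passed <- c(
    deam5 = deam_pass(metrics$deamination$p5_ct,
                      metrics$deamination$n5_informative, criteria),
    deam3 = deam_pass(metrics$deamination$p3_ga,
                      metrics$deamination$n3_informative, criteria),
    evenness = even_pass,
    edit_all = edit_decay_pass(metrics$edit_all, criteria),
    edit_damaged = edit_decay_pass(metrics$edit_damaged, criteria) &&
      sum(metrics$edit_damaged) >= criteria$edit_damaged_min_reads,
    read_length = pass_or_false(
      !is.na(metrics$read_length_median) &&
        metrics$read_length_median <= criteria$read_length_max_median),
    pmd = pass_or_false(
      length(metrics$pmd_scores) > 0 &&
        mean(metrics$pmd_scores > criteria$pmd_cut) >=
          criteria$pmd_min_frac),
    n_reads = pass_or_false(metrics$n_assigned >= criteria$n_reads_min),
    identity = pass_or_false(!is.na(metrics$ani_mean) &&
                               metrics$ani_mean >= criteria$ani_min))
  w <- unlist(weights[names(passed)])
  components <- ifelse(passed, w, 0)
  names(components) <- names(passed)
  structure(list(components = components, total = sum(components)),
            class = "auth_score")
}

#' Score matrix over samples and taxa
#'
#' @param metrics_by_sample nested named list:
#'   `metrics_by_sample[[sample]][[taxon]]` is an [auth_metrics()] bundle.
#'   Pairs absent from the list score 0.
#' @param criteria a [score_criteria()].
#' @param weights a [score_weights()].
#' @return list with `scores` (taxa x samples numeric matrix of total
#'   scores) and `components` (long data.frame of per-pair component
#'   points).
#' @export
score_matrix <- function(metrics_by_sample, criteria = score_criteria(),
                         weights = score_weights()) {
  samples <- names(metrics_by_sample)
  taxa <- sort(unique(unlist(lapply(metrics_by_sample, names))))
  if (length(taxa) == 0 || length(samples) == 0) {
    warning("no (sample, taxon) pairs to score")
    return(list(scores = matrix(numeric(0), nrow = 0, ncol = 0),
                components = data.frame()))
  }
  scores <- matrix(0, nrow = length(taxa), ncol = length(samples),
                   dimnames = list(taxa, samples))
  comp <- list()
  for (s in samples) {
    for (t in names(metrics_by_sample[[s]])) {
      sc <- score_taxon(metrics_by_sample[[s]][[t]], criteria, weights)
      scores[t, s] <- sc$total
      comp[[paste(s, t)]] <- data.frame(
        sample = s, taxon = t, component = names(sc$components),
        points = unname(sc$components), stringsAsFactors = FALSE)
    }
  }
  list(scores = scores, components = do.call(rbind, c(comp,
                                                      make.row.names = FALSE)))
}

#' Write a score matrix as TSV
#'
#' Rows are taxa, columns are samples.
#'
#' @param scores numeric matrix from [score_matrix()].
#' @param path output file.
#' @export
write_score_matrix <- function(scores, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(c("taxon", colnames(scores)), collapse = "\t"),
               vapply(seq_len(nrow(scores)), function(i) {
                 paste(c(rownames(scores)[i],
                         format_num(scores[i, ])), collapse = "\t")
               }, character(1))),
             con, sep = "\n")
  invisible(path)
}
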