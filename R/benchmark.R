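# Detection benchmarking: Jaccard / F1 between predicted and true taxon
# sets across read-count thresholds, and ROC over authentication scores.

#' Jaccard similarity (intersection over union)
#'
#' `|A intersect B| / |A union B|` between a predicted and a true taxon
#' set; defined as 1 when both sets are empty (perfect agreement).
#'
#' @param predicted,truth vectors interpreted as sets (duplicates
#'   ignored).
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(predicted, truth) {
  p <- unique(predicted); t <- unique(truth)
  if (length(p) == 0 && length(t) == 0) return(1)
  length(intersect(p, t)) / length(union(p, t))
}

#' F1 score of set detection
#'
#' Harmonic mean of precision and recall of the predicted versus true
#' taxon set: `2 P R / (P + R)`; 0 when both precision and recall are 0,
#' and 1 when both sets are empty.
#'
#' @inheritParams jaccard
#' @return fraction in `[0, 1]`.
#' @export
f1_score <- function(predicted, truth) {
  p <- unique(predicted); t <- unique(truth)
  if (length(p) == 0 && length(t) == 0) return(1)
  tp <- length(intersect(p, t))
  prec <- if (length(p)) tp / length(p) else 0
  rec <- if (length(t)) tp / length(t) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Sweep detection metrics over read-count thresholds
#'
#' At each threshold `t`, the predicted set of a sample is the taxa with
#' at least `t` assigned reads (inclusive, consistent with the screening
#' filters); Jaccard and F1 against the sample's true set are then
#' averaged across samples with their standard deviation.
#'
#' @param abundance samples x taxa numeric matrix of assigned-read counts
#'   (rownames are samples, colnames taxa).
#' @param truth named list mapping each sample to its true taxon set.
#' @param thresholds numeric vector of read-count cutoffs, sorted
#'   ascending.
#' @return data.frame with columns `threshold`, `jaccard_mean`,
#'   `jaccard_sd`, `f1_mean`, `f1_sd`.
#' @export
threshold_sweep <- function(abundance, truth, thresholds) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  samples <- rownames(abundance)
  if (is.null(samples)) stop("abundance needs sample rownames")
  out <- lapply(thresholds, function(th) {
    j <- numeric(length(samples)); f <- numeric(length(samples))
    for (i in seq_along(samples)) {
      pred <- colnames(abundance)[abundance[i, ] >= th]
      tru <- truth[[samples[i]]]
      j[i] <- jaccard(pred, tru)
      f[i] <- f1_score(pred, tru)
    }
    data.frame(threshold = th,
               jaccard_mean = mean(j), jaccard_sd = stats::sd(j),
               f1_mean = mean(f), f1_sd = stats::sd(f))
  })
  do.call(rbind, out)
}

#' ROC curve and AUC over authentication scores
#'
#' Standard receiver operating characteristic over score thresholds, with
#' tied scores grouped (one ROC point per distinct score value); the area
#' under the curve is computed by the trapezoid rule, which equals the
#' pairwise concordance estimator (concordant pairs plus half of ties
#' over positive x negative pairs).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) ground-truth labels; must contain at
#'   least one positive and one negative.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("labels must contain at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fp / nneg),
                       tpr = c(0, tp / npos))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) +
                                   points$tpr[-1]) / 2)
  list(points = points, auc = auc)
}
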