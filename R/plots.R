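# Graphical summaries: per-taxon authentication panels, score heatmap,
# threshold-sweep curves, ROC curve.

#' Multi-panel authentication plot for one taxon
#'
#' Lays out the validation/authentication summaries of an
#' [auth_metrics()] bundle: edit distance for all and damaged reads,
#' binned evenness of coverage, deamination profile, read length
#' distribution, PMD scores, and percent identity.
#'
#' @param metrics an `auth_metrics` bundle.
#' @param title plot title (e.g. "taxon / sample").
#' @return a ggplot object (patchwork-composed when patchwork is
#'   installed, otherwise a list of ggplots).
#' @export
plot_auth_panels <- function(metrics, title = "") {
  eh <- function(h, lab) {
    ggplot2::ggplot(data.frame(ed = factor(names(h), levels = names(h)),
                               n = as.numeric(h)),
                    ggplot2::aes(x = .data$ed, y = .data$n)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::labs(x = "edit distance", y = "reads", title = lab) +
      ggplot2::theme_minimal(base_size = 9)
  }
  p_ea <- eh(metrics$edit_all, "edit distance (all reads)")
  p_ed <- eh(metrics$edit_damaged, "edit distance (damaged reads)")
  bb <- metrics$coverage$bin_breadth
  p_ev <- ggplot2::ggplot(data.frame(bin = seq_along(bb), breadth = bb),
                          ggplot2::aes(x = .data$bin, y = .data$breadth)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "genome bin", y = "local breadth",
                  title = sprintf("evenness (breadth %.3f, depth %.2fX)",
                                  metrics$coverage$breadth,
                                  metrics$coverage$depth_mean)) +
    ggplot2::theme_minimal(base_size = 9)
  dm <- metrics$deamination
  dd <- rbind(data.frame(pos = seq_along(dm$p5_ct), freq = dm$p5_ct,
                         end = "5' C>T"),
              data.frame(pos = seq_along(dm$p3_ga), freq = dm$p3_ga,
                         end = "3' G>A"))
  p_dm <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$pos, y = .data$freq,
                                           colour = .data$end)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position from read end", y = "mismatch frequency",
                  title = "deamination pattern") +
    ggplot2::theme_minimal(base_size = 9)
  p_rl <- ggplot2::ggplot(data.frame(len = metrics$read_lengths),
                          ggplot2::aes(x = .data$len)) +
    ggplot2::geom_histogram(binwidth = 5, fill = "grey30") +
    ggplot2::labs(x = "read length (bp)", y = "reads",
                  title = sprintf("read length (median %d bp)",
                                  as.integer(metrics$read_length_median))) +
    ggplot2::theme_minimal(base_size = 9)
  p_pmd <- ggplot2::ggplot(data.frame(pmd = metrics$pmd_scores),
                           ggplot2::aes(x = .data$pmd)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 3, linetype = 2, colour = "red") +
    ggplot2::labs(x = "PMD score", y = "reads", title = "PMD scores") +
    ggplot2::theme_minimal(base_size = 9)
  ih <- metrics$identity_hist
  p_id <- ggplot2::ggplot(data.frame(bin = factor(names(ih),
                                                  levels = names(ih)),
                                     n = as.numeric(ih)),
                          ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "percent identity", y = "reads",
                  title = sprintf("identity (ANI %.2f%%, %d reads)",
                                  metrics$ani_mean, metrics$n_assigned)) +
    ggplot2::theme_minimal(base_size = 9)
  panels <- list(p_ea, p_ed, p_ev, p_dm, p_rl, p_pmd, p_id)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(panels, ncol = 3) +
      patchwork::plot_annotation(title = title)
  } else {
    panels
  }
}

#' Heatmap of authentication scores
#'
#' Taxa x samples tile plot with the colour scale fixed to the full 0-10
#' score range.
#'
#' @param scores numeric matrix from [score_matrix()].
#' @return a ggplot object.
#' @export
plot_score_heatmap <- function(scores) {
  d <- expand.grid(taxon = rownames(scores), sample = colnames(scores),
                   stringsAsFactors = FALSE)
  d$score <- as.vector(scores)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$taxon,
                                  fill = .data$score)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 10)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a threshold sweep
#'
#' @param sweep data.frame from [threshold_sweep()].
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  d <- rbind(data.frame(threshold = sweep$threshold,
                        mean = sweep$jaccard_mean, sd = sweep$jaccard_sd,
                        metric = "Jaccard"),
             data.frame(threshold = sweep$threshold,
                        mean = sweep$f1_mean, sd = sweep$f1_sd,
                        metric = "F1"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$mean,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, mean - sd),
                                          ymax = pmin(1, mean + sd))) +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "assigned reads threshold", y = "detection metric") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot a ROC curve
#'
#' @param roc list from [roc_curve()].
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal(base_size = 10)
}
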