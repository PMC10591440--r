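# Shared fixtures and independent oracles used across the test files.

# Build an alignment_set data.frame from parallel vectors. MD defaults to
# the all-match tag for each sequence.
make_alignments <- function(seq, pos = 0L, strand = "+", nm = 0L,
                            mapq = 60L, md = NULL, ref_id = "ref") {
  n <- length(seq)
  if (is.null(md)) md <- as.character(nchar(seq))
  out <- data.frame(read_id = sprintf("r%03d", seq_len(n)),
                    ref_id = rep_len(ref_id, n),
                    pos = as.integer(rep_len(pos, n)),
                    strand = rep_len(strand, n),
                    seq = seq,
                    edit_distance = as.integer(rep_len(nm, n)),
                    mapq = as.integer(rep_len(mapq, n)),
                    md = rep_len(md, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_set", "data.frame")
  out
}

# Analytic terminal and interior C->T rates under the geometric-overhang
# Briggs convention used by the simulator (independent closed form).
briggs_interior_ct_rate <- function(p) {
  p$ds_deam + (1 - p$ds_deam) * p$nick_rate * p$ss_deam
}
briggs_terminal_ct_rate <- function(p) {
  p_overhang <- 1 - p$overhang_param   # P(overhang length >= 1)
  p_overhang * p$ss_deam + (1 - p_overhang) * briggs_interior_ct_rate(p)
}

# Exhaustive pairwise-concordance AUC estimator:
# (concordant pairs + half ties) / (positives x negatives).
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Synthetic auth_metrics bundle passing exactly the named criteria under
# the default thresholds. Unnamed criteria are constructed to fail.
make_metrics <- function(pass = character()) {
  on <- function(x) x %in% pass
  deam_freq <- function(ok) {
    if (ok) c(0.25, 0.15, rep(0.02, 13)) else c(0.0, 0.0, rep(0.02, 13))
  }
  deam <- structure(list(
    p5_ct = deam_freq(on("deam5")),
    p3_ga = deam_freq(on("deam3")),
    n5_informative = rep(1000L, 15),
    n3_informative = rep(1000L, 15),
    P = 15L), class = "deamination_profile")
  cov <- if (on("evenness")) {
    structure(list(depth_mean = 1, breadth = 0.6,
                   bin_breadth = rep(0.6, 100),
                   bin_sizes = rep(10L, 100), ref_length = 1000L),
              class = "coverage_profile")
  } else {
    structure(list(depth_mean = 1, breadth = 0.05,
                   bin_breadth = c(rep(1, 5), rep(0, 95)) * 0.05 * 20,
                   bin_sizes = rep(10L, 100), ref_length = 1000L),
              class = "coverage_profile")
  }
  hist_named <- function(x) setNames(as.integer(x), as.character(0:10))
  edit_all <- if (on("edit_all"))
    hist_named(c(500, 300, 100, 50, rep(0, 7))) else
    hist_named(c(10, 20, 30, 500, rep(0, 7)))
  edit_damaged <- if (on("edit_damaged"))
    hist_named(c(100, 60, 20, 5, rep(0, 7))) else
    hist_named(rep(0, 11))
  auth_metrics(
    deamination = deam, coverage = cov,
    edit_all = edit_all, edit_damaged = edit_damaged,
    read_lengths = rep(if (on("read_length")) 45L else 150L, 11),
    pmd_scores = if (on("pmd")) c(rep(5, 30), rep(-1, 70)) else
      rep(-1, 100),
    n_assigned = if (on("n_reads")) 1000L else 50L,
    identity_hist = setNames(c(0L, 0L, 10L, 990L),
                             c("[80,85)", "[85,90)", "[90,95)",
                               "[95,100]")),
    ani_mean = if (on("identity")) 97 else 85)
}

all_criteria <- c("deam5", "deam3", "evenness", "edit_all",
                  "edit_damaged", "read_length", "pmd", "n_reads",
                  "identity")

# Small single-species simulation shared by several tests.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- default_species_set(20000L)[c(1, 19), ]
      sp$relative_abundance <- 0.8 * c(0.5, 0.5)
      des <- sample_design("tst", n_ancient_fragments = 4000L,
                           n_modern_fragments = 4000L,
                           microbial_fraction = 0.8, seed = 101L)
      cache <<- list(sim = simulate_sample(des, sp), species = sp,
                     design = des)
    }
    cache
  }
})
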