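# End-to-end driver: simulate -> screen -> authenticate -> score ->
# benchmark, plus YAML run configuration.

run_config_defaults <- function() {
  list(out_dir = "paleosift_run",
       seed = 1L,
       n_samples = 10L,
       scale = 1,
       n_species = NULL,
       host_genome_length = 500000L,
       species_genome_length = 100000L,
       kmer_k = 31L,
       min_unique_kmers = 1000,
       min_tax_reads = 200,
       rank_keep = "species",
       n_bins = 100L,
       deamination_window = 15L,
       terminal_window = 5L,
       sweep_thresholds = c(1, 10, 50, 100, 200, 300, 500, 1000),
       preprocess = TRUE,
       min_read_length = 31L,
       make_plots = TRUE,
       verbose = TRUE)
}

#' Run configuration
#'
#' Builds the configuration consumed by [run_end_to_end()], optionally
#' layering a YAML file and direct overrides on top of the defaults.
#' Unknown keys are rejected. Defaults match the screening and scoring
#' defaults throughout the package: 1000 unique k-mers, 200 assigned
#' reads, `k = 31`, 100 evenness bins, and the 0-10 score weights.
#'
#' @param path optional YAML file whose keys override the defaults.
#' @param ... direct key overrides (applied after the file).
#' @return an object of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- run_config_defaults()
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Build a classifier-style report from truth alignments
#'
#' Stands in for an external k-mer classifier on synthetic data: each
#' species present in the sample's truth alignments becomes one
#' species-rank report row with `taxReads` equal to its alignment count
#' and `kmers` equal to the distinct reference k-mers its alignments
#' cover (see [count_unique_kmers_covered()]). This is an idealised
#' classification (every read assigned to its true genome); real
#' classifier output can be supplied to [filter_candidates()] directly
#' via [read_krakenuniq_report()].
#'
#' @param alignments truth `alignment_set` of one sample.
#' @param species species table with `name` and `taxid` columns.
#' @param genomes named character vector of genomes.
#' @param k k-mer length.
#' @return data.frame in the classifier report layout.
#' @export
report_from_truth <- function(alignments, species, genomes, k = 31L) {
  rows <- lapply(seq_len(nrow(species)), function(i) {
    sp <- species$name[i]
    a <- alignments[alignments$ref_id == sp, , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    data.frame(pct = 0, reads = nrow(a), taxReads = nrow(a),
               kmers = count_unique_kmers_covered(a, genomes[[sp]], k),
               dup = 1, cov = 0, taxID = species$taxid[i],
               rank = "species", taxName = sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(read_krakenuniq_report(textConnection_empty()))
  out$pct <- round(100 * out$reads / sum(out$reads), 4)
  out
}

textConnection_empty <- function() {
  f <- tempfile()
  writeLines(character(0), f)
  f
}

#' Run the full synthetic evaluation pipeline
#'
#' Simulates samples with ground truth, derives classifier-style reports,
#' filters candidates by depth and breadth of coverage, computes
#' authentication metrics and 0-10 scores per candidate, and benchmarks
#' detection (threshold sweep) and authentication (ROC of scores against
#' the ancient/modern ground truth, with present ancient taxa as
#' positives and present modern taxa as negatives). All outputs are
#' written under `config$out_dir`; two runs with the same configuration
#' and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `scores`, `sweep`, `roc`, `truth`,
#'   `out_dir`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir) || !nzchar(out_dir))
    stop("config$out_dir must be a non-empty path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (isTRUE(config$verbose))
      message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg)
  }
  log("stage: configure; seed=", config$seed, " n_samples=",
      config$n_samples, " scale=", config$scale)

  species <- default_species_set(config$species_genome_length)
  if (!is.null(config$n_species) && config$n_species < nrow(species)) {
    # balanced reduced panel: half ancient, half modern
    n_anc <- ceiling(config$n_species / 2)
    n_mod <- config$n_species - n_anc
    species <- rbind(head(species[species$is_ancient, ], n_anc),
                     head(species[!species$is_ancient, ], n_mod))
    rownames(species) <- NULL
  }
  study <- default_study_design(seed = config$seed, scale = config$scale,
                                species = species,
                                n_samples = config$n_samples)
  genomes <- generate_genomes(species, config$host_genome_length,
                              seed = config$seed)
  write_fasta(genomes, file.path(out_dir, "genomes.fasta"))
  fcfg <- filter_config(config$min_unique_kmers, config$min_tax_reads,
                        config$rank_keep)

  sim_dir <- file.path(out_dir, "sim")
  truth_all <- list()
  abundance <- list()
  truth_sets <- list()
  metrics_by_sample <- list()
  for (s in study$samples) {
    id <- s$design$sample_id
    log("stage: simulate; sample=", id, " fragments=",
        s$design$n_ancient_fragments + s$design$n_modern_fragments,
        " microbial_fraction=", s$design$microbial_fraction)
    sim <- simulate_sample(s$design, s$species, genomes = genomes,
                           out_dir = sim_dir)
    truth_all[[id]] <- sim$truth

    if (isTRUE(config$preprocess)) {
      reads <- read_fastq(sim$fastq_r1)
      n0 <- nrow(reads)
      reads <- trim_adapter(reads, s$design$adapter_seq)
      reads <- filter_reads_by_length(reads, config$min_read_length)
      write_fastq(reads, file.path(sim_dir,
                                   paste0(id, "_R1.trimmed.fastq")))
      log("stage: preprocess; sample=", id, " reads_in=", n0,
          " reads_kept=", nrow(reads), " min_len=",
          config$min_read_length)
    }

    log("stage: screen; sample=", id, " min_kmers=",
        config$min_unique_kmers, " min_taxreads=", config$min_tax_reads)
    report <- report_from_truth(sim$alignments, species, genomes,
                                config$kmer_k)
    write_krakenuniq_report(report,
                            file.path(out_dir,
                                      paste0(id, ".report.tsv")))
    cand <- filter_candidates(report, fcfg)
    write_candidates(cand, file.path(out_dir,
                                     paste0(id, ".candidates.tsv")))

    abundance[[id]] <- setNames(report$taxReads, report$taxName)
    tr <- sim$truth
    truth_sets[[id]] <- tr$species[tr$species != "host" &
                                     tr$n_fragments > 0]

    log("stage: metrics; sample=", id, " candidates=", nrow(cand))
    mdir <- file.path(out_dir, "metrics", id)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    sm <- list()
    for (taxon in cand$taxName) {
      a <- sim$alignments[sim$alignments$ref_id == taxon, , drop = FALSE]
      m <- compute_auth_metrics(a, nchar(genomes[[taxon]]),
                                n_bins = config$n_bins,
                                P = config$deamination_window,
                                terminal_window = config$terminal_window)
      sm[[taxon]] <- m
      safe <- gsub("[^A-Za-z0-9]+", "_", taxon)
      write_auth_metrics(m, file.path(mdir, paste0(safe, ".tsv")))
      if (isTRUE(config$make_plots))
        ggplot2::ggsave(file.path(mdir, paste0(safe, ".png")),
                        plot_auth_panels(m, paste(taxon, "/", id)),
                        width = 10, height = 7, dpi = 100)
    }
    metrics_by_sample[[id]] <- sm
  }

  log("stage: score")
  scored <- score_matrix(metrics_by_sample)
  write_score_matrix(scored$scores, file.path(out_dir, "scores.tsv"))
  if (nrow(scored$components))
    write_tsv_plain(scored$components,
                    file.path(out_dir, "score_components.tsv"))
  if (isTRUE(config$make_plots) && nrow(scored$scores))
    ggplot2::ggsave(file.path(out_dir, "scores_heatmap.png"),
                    plot_score_heatmap(scored$scores),
                    width = 8, height = 6, dpi = 100)

  log("stage: benchmark")
  taxa <- species$name
  ab <- matrix(0, nrow = length(abundance), ncol = length(taxa),
               dimnames = list(names(abundance), taxa))
  for (id in names(abundance)) {
    hit <- intersect(names(abundance[[id]]), taxa)
    ab[id, hit] <- abundance[[id]][hit]
  }
  sweep <- threshold_sweep(ab, truth_sets, config$sweep_thresholds)
  write_tsv_plain(sweep, file.path(out_dir, "sweep.tsv"))
  if (isTRUE(config$make_plots))
    ggplot2::ggsave(file.path(out_dir, "sweep.png"), plot_sweep(sweep),
                    width = 6, height = 4, dpi = 100)

  truth_df <- do.call(rbind, truth_all)
  rownames(truth_df) <- NULL
  write_tsv_plain(truth_df, file.path(out_dir, "truth.tsv"))
  pres <- truth_df[truth_df$species != "host" & truth_df$n_fragments > 0, ]
  sc <- numeric(nrow(pres))
  for (i in seq_len(nrow(pres))) {
    sc[i] <- if (nrow(scored$scores) &&
                 pres$species[i] %in% rownames(scored$scores) &&
                 pres$sample[i] %in% colnames(scored$scores)) {
      scored$scores[pres$species[i], pres$sample[i]]
    } else 0
  }
  roc <- NULL
  if (any(pres$is_ancient) && any(!pres$is_ancient)) {
    roc <- roc_curve(sc, pres$is_ancient)
    write_tsv_plain(roc$points, file.path(out_dir, "roc.tsv"))
    if (isTRUE(config$make_plots))
      ggplot2::ggsave(file.path(out_dir, "roc.png"), plot_roc(roc),
                      width = 5, height = 5, dpi = 100)
    log("stage: benchmark; roc_auc=", format_num_full(roc$auc))
  } else {
    log("stage: benchmark; roc skipped (single-class ground truth)")
  }

  con <- file(log_path, "wb")
  writeLines(log_lines, con, sep = "\n")
  close(con)
  invisible(list(scores = scored$scores, sweep = sweep, roc = roc,
                 truth = truth_df, out_dir = out_dir))
}

write_tsv_plain <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) format_num_full(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  writeLines(c(paste(names(df), collapse = "\t"),
               apply(cells, 1, paste, collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}
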