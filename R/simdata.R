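# Simulation of ancient metagenomic samples: Briggs-model damage,
# log-normal fragmentation, adapter read-through, ground truth bookkeeping.

#' Briggs damage model parameters
#'
#' Parameters of the post-mortem damage model applied to ancient fragments:
#' single-strand overhangs with geometrically distributed lengths, elevated
#' C-to-T deamination inside the 5' overhang (seen as G-to-A inside the 3'
#' overhang), background double-strand deamination in the interior, and
#' nicks that open additional single-strand deamination opportunities.
#'
#' @param nick_rate per-position probability of a nick in the
#'   double-stranded interior; a nicked C gets an additional
#'   single-strand-rate deamination opportunity (fragments are never split,
#'   so truth fragment counts stay exact).
#' @param overhang_param parameter `p` of the geometric overhang-length
#'   distribution `P(len = j) = p (1-p)^j`, `j >= 0` (blunt ends allowed).
#' @param ds_deam per-site C-to-T deamination probability in the
#'   double-stranded interior.
#' @param ss_deam per-site C-to-T deamination probability inside a
#'   single-strand overhang (G-to-A at the 3' end).
#' @return an object of class `damage_params`.
#' @export
damage_params <- function(nick_rate = 0.03, overhang_param = 0.4,
                          ds_deam = 0.01, ss_deam = 0.3) {
  vals <- c(nick_rate = nick_rate, overhang_param = overhang_param,
            ds_deam = ds_deam, ss_deam = ss_deam)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all damage parameters must lie in [0, 1]")
  if (ss_deam < ds_deam)
    warning("ss_deam < ds_deam: overhang damage weaker than background")
  structure(as.list(vals), class = "damage_params")
}

#' Log-normal fragment length model
#'
#' Fragment lengths are drawn as `round(exp(Normal(loc, scale)))` and
#' floored at `min_len`. The default location/scale were determined
#' empirically from ancient *Yersinia pestis* reads (median about 42 bp).
#'
#' @param loc log-scale location parameter.
#' @param scale log-scale standard deviation (> 0).
#' @param min_len integer floor on sampled lengths; fragments below the
#'   k-mer taxonomic-specificity scale are uninformative.
#' @return an object of class `fragment_length_model`.
#' @export
fragment_length_model <- function(loc = 3.7424069808, scale = 0.2795148843,
                                  min_len = 30L) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (min_len < 1) stop("min_len must be >= 1")
  structure(list(loc = loc, scale = scale, min_len = as.integer(min_len)),
            class = "fragment_length_model")
}

#' Fragment length model for modern (contaminant) DNA
#'
#' Modern contaminants are moderately fragmented: longer fragments than
#' ancient DNA and no damage. The default gives a median of about 120 bp.
#'
#' @inheritParams fragment_length_model
#' @export
modern_fragment_length_model <- function(loc = log(120), scale = 0.3,
                                         min_len = 30L) {
  fragment_length_model(loc = loc, scale = scale, min_len = min_len)
}

#' Per-sample simulation design
#'
#' @param sample_id character label for the sample.
#' @param n_ancient_fragments number of ancient-pool DNA fragments.
#' @param n_modern_fragments number of modern-pool DNA fragments.
#' @param microbial_fraction fraction of fragments (in each pool) that are
#'   microbial; the remainder is host DNA.
#' @param read_length length in bp of each emitted raw read.
#' @param paired emit paired-end reads (R1/R2)?
#' @param adapter_seq adapter appended when a fragment is shorter than the
#'   read length (read-through), followed by random fill.
#' @param error_rate uniform per-base substitution sequencing-error rate.
#' @param seed master integer seed for this sample; per-species substreams
#'   are derived from it deterministically.
#' @return an object of class `sample_design`.
#' @export
sample_design <- function(sample_id = "sample1",
                          n_ancient_fragments = 500000L,
                          n_modern_fragments = 500000L,
                          microbial_fraction = 0.5,
                          read_length = 125L,
                          paired = TRUE,
                          adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                          error_rate = 0.001,
                          seed = 1L) {
  if (microbial_fraction < 0 || microbial_fraction > 1)
    stop("microbial_fraction must lie in [0, 1]")
  if (read_length <= 0) stop("read_length must be > 0")
  if (n_ancient_fragments < 0 || n_modern_fragments < 0)
    stop("fragment counts must be >= 0")
  structure(list(sample_id = sample_id,
                 n_ancient_fragments = as.integer(n_ancient_fragments),
                 n_modern_fragments = as.integer(n_modern_fragments),
                 microbial_fraction = microbial_fraction,
                 read_length = as.integer(read_length),
                 paired = isTRUE(paired),
                 adapter_seq = toupper(adapter_seq),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sample_design")
}

#' Default 35-species study composition
#'
#' The default species panel mirrors taxa commonly encountered in ancient
#' metagenomic projects: 18 species flagged ancient (host-associated or
#' exogenous environmental bacteria with damage) and 17 modern
#' contaminants (e.g. *Burkholderia* and *Pseudomonas* species typical of
#' laboratory negative controls). Genome sequences are synthetic
#' (see [generate_genomes()]); only names and labels reproduce the field
#' panel.
#'
#' @param genome_length synthetic genome length in bp assigned to every
#'   species.
#' @return data.frame with columns `name`, `taxid`, `is_ancient`,
#'   `genome_length`.
#' @export
default_species_set <- function(genome_length = 100000L) {
  ancient <- c(
    "Campylobacter rectus", "Clostridium botulinum",
    "Enterococcus faecalis", "Fusarium fujikuroi", "Mycobacterium avium",
    "Mycolicibacterium aurum", "Neisseria meningitidis",
    "Nocardia brasiliensis", "Parvimonas micra",
    "Prosthecobacter vanneervenii", "Ralstonia solanacearum",
    "Rothia dentocariosa", "Salmonella enterica", "Sorangium cellulosum",
    "Streptococcus pyogenes", "Streptosporangium roseum",
    "Yersinia pestis", "Bradyrhizobium erythrophlei")
  modern <- c(
    "Acanthamoeba castellanii", "Aspergillus flavus",
    "Brevibacterium aurantiacum", "Burkholderia mallei",
    "Lactococcus lactis", "Methylobacterium bullatum",
    "Micromonas commoda", "Micromonospora echinospora",
    "Nonomuraea gerenzanensis", "Pseudomonas caeni",
    "Pseudomonas psychrophila", "Pseudomonas thivervalensis",
    "Vermamoeba vermiformis", "Rhodococcus hoagii",
    "Rhodopseudomonas palustris", "Mycobacterium riyadhense",
    "Planobispora rosea")
  nm <- c(ancient, modern)
  data.frame(name = nm,
             taxid = 1000L + seq_along(nm),
             is_ancient = rep(c(TRUE, FALSE), c(length(ancient), length(modern))),
             genome_length = as.integer(genome_length),
             stringsAsFactors = FALSE)
}

#' Default ten-sample study design
#'
#' Ten samples, each with 500,000 ancient and 500,000 modern fragments
#' (scaled by `scale`), with the total microbial DNA fraction varying as
#' 0.7, 0.7, 0.7, 0.5, 0.5, 0.5, 0.4, 0.3, 0.3, 0.3 across samples; the
#' remaining fragments are host DNA. Per-sample species abundances are set
#' randomly (uniform, normalised to the microbial fraction) from the study
#' seed.
#'
#' @param seed master study seed.
#' @param scale multiplier on fragment counts; `scale = 0.01` gives a fast
#'   1 percent scale run with the same composition structure.
#' @param species species table as from [default_species_set()].
#' @param n_samples number of samples (fractions recycle the default
#'   pattern if fewer than 10).
#' @return list with elements `samples` (list of per-sample lists holding
#'   `design` and `species`, where `species` gains a `relative_abundance`
#'   column summing to the sample's microbial fraction) and `species`
#'   (the panel table).
#' @export
default_study_design <- function(seed = 1L, scale = 1,
                                 species = default_species_set(),
                                 n_samples = 10L) {
  fracs <- rep_len(c(0.7, 0.7, 0.7, 0.5, 0.5, 0.5, 0.4, 0.3, 0.3, 0.3),
                   n_samples)
  n_frag <- max(1L, as.integer(round(500000 * scale)))
  samples <- lapply(seq_len(n_samples), function(i) {
    sseed <- derive_seed(seed, i)
    ab <- withr::with_seed(sseed, runif(nrow(species)))
    sp <- species
    sp$relative_abundance <- fracs[i] * ab / sum(ab)
    list(design = sample_design(sample_id = sprintf("sample%02d", i),
                                n_ancient_fragments = n_frag,
                                n_modern_fragments = n_frag,
                                microbial_fraction = fracs[i],
                                seed = sseed),
         species = sp)
  })
  list(samples = samples, species = species)
}

# Deterministic sub-seed derivation so per-species random streams do not
# depend on iteration order. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (x in c(...)) {
    h <- (h * 31 + as.numeric(x) + 7) %% 2147483629
  }
  as.integer(h) + 1L
}

#' Generate a random reference sequence
#'
#' @param length sequence length in bp (> 0).
#' @param gc target GC content in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return a single uppercase A/C/G/T string of exactly `length` bases.
#' @export
generate_reference <- function(length, gc = 0.5, seed = 1L) {
  if (length(length) != 1 || !is.finite(length) || length <= 0)
    stop("length must be a single positive number")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  withr::with_seed(seed, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
}

#' Generate named synthetic genomes for a species panel
#'
#' One genome per species plus a `host` genome, each deterministic in the
#' study seed and the species' taxid.
#'
#' @param species data.frame with columns `name`, `taxid`, `genome_length`.
#' @param host_genome_length length of the synthetic host genome.
#' @param seed study seed.
#' @param gc GC content of all genomes.
#' @return named character vector of genome sequences (names are species
#'   names plus `"host"`).
#' @export
generate_genomes <- function(species, host_genome_length = 500000L,
                             seed = 1L, gc = 0.5) {
  g <- vapply(seq_len(nrow(species)), function(i) {
    generate_reference(species$genome_length[i], gc = gc,
                       seed = derive_seed(seed, species$taxid[i]))
  }, character(1))
  names(g) <- species$name
  c(g, host = generate_reference(host_genome_length, gc = gc,
                                 seed = derive_seed(seed, 9606L)))
}

#' Sample fragment lengths from a log-normal model
#'
#' @param n number of lengths to draw.
#' @param model a [fragment_length_model()].
#' @param seed integer seed.
#' @return integer vector of `n` lengths, each `>= model$min_len`.
#' @export
sample_fragment_lengths <- function(n, model = fragment_length_model(),
                                    seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(integer(0))
  withr::with_seed(seed, {
    pmax(model$min_len, as.integer(round(rlnorm(n, model$loc, model$scale))))
  })
}

# --- Briggs damage -----------------------------------------------------

# Batch damage over a character vector of fragments. Returns list(seq =
# damaged fragments, events = data.frame(fragment, pos, from, to, zone)).
damage_fragments <- function(frags, params) {
  lens <- nchar(frags)
  nf <- length(frags)
  if (nf == 0)
    return(list(seq = character(0),
                events = data.frame(fragment = integer(0), pos = integer(0),
                                    from = character(0), to = character(0),
                                    zone = character(0))))
  ch <- strsplit(frags, "", fixed = TRUE)
  flat <- unlist(ch, use.names = FALSE)
  frag_id <- rep.int(seq_len(nf), lens)
  pos5 <- sequence(lens)                  # 1-based distance from 5' end
  pos3 <- rep.int(lens, lens) - pos5 + 1L # 1-based distance from 3' end

  p <- params$overhang_param
  o5 <- rgeom(nf, p)
  o3 <- rgeom(nf, p)
  in5 <- pos5 <= o5[frag_id]
  in3 <- pos3 <= o3[frag_id] & !in5      # 5' overhang takes precedence
  interior <- !in5 & !in3

  # effective interior C->T rate: background ds deamination plus a nick
  # opening a single-strand opportunity at the nicked site
  r_int <- params$ds_deam +
    (1 - params$ds_deam) * params$nick_rate * params$ss_deam

  u <- runif(length(flat))
  ct5 <- flat == "C" & in5 & u < params$ss_deam
  ctd <- flat == "C" & !in5 & interior & u < r_int
  ga3 <- flat == "G" & in3 & u < params$ss_deam

  out <- flat
  out[ct5 | ctd] <- "T"
  out[ga3] <- "A"

  hit <- which(ct5 | ctd | ga3)
  events <- data.frame(
    fragment = frag_id[hit],
    pos = pos5[hit],
    from = flat[hit],
    to = out[hit],
    zone = ifelse(ct5[hit], "overhang5",
                  ifelse(ga3[hit], "overhang3", "interior")),
    stringsAsFactors = FALSE)

  seqs <- vapply(split(out, factor(frag_id, levels = seq_len(nf))),
                 paste, character(1), collapse = "")
  names(seqs) <- NULL
  list(seq = seqs, events = events)
}

#' Apply Briggs-model post-mortem damage to a fragment
#'
#' Draws a single-strand overhang length for each fragment end from a
#' geometric distribution (`P(len = j) = p (1-p)^j`, blunt ends allowed),
#' then deaminates: C-to-T at `ss_deam` inside the 5' overhang, G-to-A at
#' `ss_deam` inside the 3' overhang (the complementary strand's C-to-T),
#' and C-to-T at the effective interior rate
#' `ds_deam + (1 - ds_deam) * nick_rate * ss_deam` in the double-stranded
#' interior (background deamination plus nick-opened single-strand
#' opportunities). Fragment length is never changed; non-ACGT characters
#' pass through unmodified.
#'
#' @param fragment a nucleotide string, or a character vector of fragments
#'   to damage in one batch.
#' @param params a [damage_params()] object.
#' @param seed integer seed.
#' @return list with `seq` (damaged fragment(s)) and `events` (data.frame
#'   of position from the 5' end, original base, new base, and zone of
#'   each substitution; with a `fragment` index column for batch input).
#' @export
apply_briggs_damage <- function(fragment, params = damage_params(),
                                seed = 1L) {
  if (length(fragment) == 0 || any(!nzchar(fragment)))
    stop("fragments must be non-empty strings")
  res <- withr::with_seed(seed, damage_fragments(fragment, params))
  if (length(fragment) == 1)
    res$events <- res$events[, c("pos", "from", "to", "zone")]
  res
}

# --- Sequence helpers --------------------------------------------------

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform substitution errors across a character vector of sequences.
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  ch <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(ch, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate & flat %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- ceiling(runif(length(hit)) * 3)
    flat[hit] <- vapply(seq_along(hit), function(i) {
      alt[[flat[hit[i]]]][pick[i]]
    }, character(1))
  }
  frag_id <- rep.int(seq_along(seqs), lens)
  out <- vapply(split(flat, factor(frag_id, levels = seq_along(seqs))),
                paste, character(1), collapse = "")
  names(out) <- NULL
  out
}

random_bases <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Largest-remainder apportionment of n items over non-negative weights.
apportion <- function(n, weights) {
  if (n == 0 || length(weights) == 0) return(integer(length(weights)))
  s <- sum(weights)
  if (s <= 0) {
    out <- integer(length(weights))
    out[1] <- n
    return(out)
  }
  exact <- n * weights / s
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# MD tag for a gapless alignment given reference and read character
# vectors of equal length.
md_tag <- function(ref_ch, read_ch) {
  mm <- which(ref_ch != read_ch)
  if (length(mm) == 0) return(as.character(length(ref_ch)))
  parts <- character(2 * length(mm) + 1)
  prev <- 0L
  for (i in seq_along(mm)) {
    parts[2 * i - 1] <- as.character(mm[i] - prev - 1L)
    parts[2 * i] <- ref_ch[mm[i]]
    prev <- mm[i]
  }
  parts[2 * length(mm) + 1] <- as.character(length(ref_ch) - prev)
  paste(parts, collapse = "")
}

# --- Sample simulation -------------------------------------------------

#' Simulate one ancient metagenomic sample
#'
#' Generates `n_ancient_fragments` fragments from the ancient pool (ancient
#' species plus host, damaged and short-fragmented) and
#' `n_modern_fragments` from the modern pool (modern species plus host,
#' moderately fragmented, no damage), then emits sequencing reads, a
#' ground-truth table, and a truth SAM recording every fragment's origin.
#' Fragments are apportioned so per-pool totals are exact: within each
#' pool the host receives `1 - microbial_fraction` of the fragments and
#' the pool's species share the rest in proportion to their relative
#' abundances.
#'
#' Reads are exactly `read_length` bases: a fragment shorter than the read
#' is padded with the adapter and then random bases (adapter
#' read-through). Uniform substitution sequencing errors are applied to
#' template-derived bases. With `paired = TRUE`, R2 is the
#' reverse-complement read of the same fragment.
#'
#' @param design a [sample_design()].
#' @param species data.frame with columns `name`, `taxid`, `is_ancient`,
#'   `genome_length`, `relative_abundance`; abundances must sum to
#'   `design$microbial_fraction`.
#' @param damage a [damage_params()] for ancient-pool fragments.
#' @param fraglen ancient-pool [fragment_length_model()].
#' @param modern_fraglen modern-pool fragment length model.
#' @param genomes named character vector of genome sequences (one per
#'   species name plus `"host"`); generated from `design$seed` if `NULL`.
#' @param out_dir directory for FASTQ/TSV/SAM output, or `NULL` to skip
#'   writing files.
#' @return (invisibly) a list with `truth` (data.frame: sample, taxid,
#'   species, is_ancient, n_fragments), `alignments` (truth alignments as
#'   an `alignment set` data.frame, see [read_sam()]), `genomes`, and any
#'   file paths written (`fastq_r1`, `fastq_r2`, `truth_tsv`, `sam`).
#' @export
simulate_sample <- function(design, species,
                            damage = damage_params(),
                            fraglen = fragment_length_model(),
                            modern_fraglen = modern_fragment_length_model(),
                            genomes = NULL, out_dir = NULL) {
  stopifnot(inherits(design, "sample_design"))
  need <- c("name", "taxid", "is_ancient", "genome_length",
            "relative_abundance")
  if (!all(need %in% names(species)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  if (abs(sum(species$relative_abundance) - design$microbial_fraction) > 1e-6)
    stop("species relative abundances must sum to the microbial fraction (",
         design$microbial_fraction, "), got ",
         sum(species$relative_abundance))
  if (is.null(genomes))
    genomes <- generate_genomes(species, seed = design$seed)
  missing_g <- setdiff(c(species$name, "host"), names(genomes))
  if (length(missing_g))
    stop("missing genomes for: ", paste(missing_g, collapse = ", "))

  pools <- list(
    ancient = list(n = design$n_ancient_fragments,
                   sp = species[species$is_ancient, , drop = FALSE],
                   model = fraglen, damaged = TRUE),
    modern = list(n = design$n_modern_fragments,
                  sp = species[!species$is_ancient, , drop = FALSE],
                  model = modern_fraglen, damaged = FALSE))

  truth <- list(); aln <- list(); reads1 <- list(); reads2 <- list()
  for (pool_name in names(pools)) {
    pool <- pools[[pool_name]]
    mf <- design$microbial_fraction
    sp <- pool$sp
    w_sp <- if (nrow(sp) && sum(sp$relative_abundance) > 0) {
      mf * sp$relative_abundance / sum(sp$relative_abundance)
    } else numeric(0)
    entities <- data.frame(
      name = c(sp$name, "host"),
      taxid = c(sp$taxid, 9606L),
      weight = c(w_sp, 1 - mf),
      stringsAsFactors = FALSE)
    counts <- apportion(pool$n, entities$weight)
    truth[[pool_name]] <- data.frame(
      sample = design$sample_id,
      taxid = entities$taxid,
      species = entities$name,
      is_ancient = pool_name == "ancient",
      n_fragments = counts,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(entities))) {
      n <- counts[i]
      if (n == 0) next
      ent <- entities$name[i]
      sub_seed <- derive_seed(design$seed, entities$taxid[i],
                              if (pool_name == "ancient") 1L else 2L)
      frag <- withr::with_seed(sub_seed, {
        genome <- genomes[[ent]]
        glen <- nchar(genome)
        lens <- pmin(glen,
                     sample_fragment_lengths(n, pool$model,
                                             seed = derive_seed(sub_seed, 1L)))
        starts <- floor(runif(n) * (glen - lens + 1)) + 1L
        minus <- runif(n) < 0.5
        ref_slice <- substring(genome, starts, starts + lens - 1L)
        fr <- ref_slice
        fr[minus] <- revcomp(fr[minus])
        if (pool$damaged) fr <- damage_fragments(fr, damage)$seq
        fr <- add_substitution_errors(fr, design$error_rate)
        list(seq = fr, ref = ref_slice, start = starts, minus = minus,
             len = lens)
      })
      ids <- sprintf("%s_%s_%s_%06d", design$sample_id,
                     gsub("[^A-Za-z0-9]+", "_", ent),
                     substr(pool_name, 1, 3), seq_len(n))
      seq_fwd <- frag$seq
      seq_fwd[frag$minus] <- revcomp(seq_fwd[frag$minus])
      nm <- integer(n); md <- character(n)
      rc <- strsplit(frag$ref, "", fixed = TRUE)
      sc <- strsplit(seq_fwd, "", fixed = TRUE)
      for (j in seq_len(n)) {
        nm[j] <- sum(rc[[j]] != sc[[j]])
        md[j] <- md_tag(rc[[j]], sc[[j]])
      }
      aln[[paste(pool_name, ent, sep = "\r")]] <- data.frame(
        read_id = ids, ref_id = ent, pos = frag$start - 1L,
        strand = ifelse(frag$minus, "-", "+"),
        seq = seq_fwd, edit_distance = nm, mapq = 60L, md = md,
        stringsAsFactors = FALSE)
      rd <- withr::with_seed(derive_seed(sub_seed, 2L), {
        build_reads(frag$seq, design)
      })
      reads1[[paste(pool_name, ent, sep = "\r")]] <-
        data.frame(id = ids, seq = rd$r1, stringsAsFactors = FALSE)
      if (design$paired)
        reads2[[paste(pool_name, ent, sep = "\r")]] <-
          data.frame(id = ids, seq = rd$r2, stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  alignments <- if (length(aln)) do.call(rbind, aln) else
    empty_alignments()
  rownames(alignments) <- NULL
  class(alignments) <- c("alignment_set", "data.frame")
  r1 <- do.call(rbind, reads1)
  r2 <- if (design$paired) do.call(rbind, reads2) else NULL

  out <- list(truth = truth, alignments = alignments, genomes = genomes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(out_dir, design$sample_id)
    out$fastq_r1 <- paste0(base, "_R1.fastq")
    write_fastq(data.frame(id = r1$id, seq = r1$seq,
                           qual = strrep("I", nchar(r1$seq))), out$fastq_r1)
    if (design$paired) {
      out$fastq_r2 <- paste0(base, "_R2.fastq")
      write_fastq(data.frame(id = r2$id, seq = r2$seq,
                             qual = strrep("I", nchar(r2$seq))), out$fastq_r2)
    }
    out$truth_tsv <- paste0(base, "_truth.tsv")
    write.table(truth, out$truth_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$sam <- paste0(base, "_truth.sam")
    write_sam(alignments, genomes, out$sam)
  }
  invisible(out)
}

# Build fixed-length reads from fragments: fragment, then adapter, then
# random fill, truncated to read_length. R2 reads the reverse complement.
build_reads <- function(frags, design) {
  L <- design$read_length
  one <- function(fr) {
    vapply(fr, function(s) {
      n <- nchar(s)
      if (n >= L) return(substr(s, 1L, L))
      s <- paste0(s, substr(design$adapter_seq, 1L, L - n))
      n <- nchar(s)
      if (n < L) s <- paste0(s, random_bases(L - n))
      s
    }, character(1), USE.NAMES = FALSE)
  }
  r1 <- one(frags)
  r2 <- if (design$paired) one(revcomp(frags)) else NULL
  list(r1 = r1, r2 = r2)
}
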