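test_that("generate_reference honours length, composition and seed", {
  s <- generate_reference(100, gc = 0.5, seed = 1)
  expect_equal(nchar(s), 100)
  expect_true(grepl("^[ACGT]+$", s))
  expect_identical(s, generate_reference(100, gc = 0.5, seed = 1))
  expect_false(identical(s, generate_reference(100, gc = 0.5, seed = 2)))
  at_only <- generate_reference(10, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only))
  expect_error(generate_reference(0), "positive")
})

test_that("fragment lengths follow the log-normal model", {
  expect_identical(sample_fragment_lengths(0), integer(0))
  m <- fragment_length_model()
  l <- sample_fragment_lengths(100000, m, seed = 3)
  # closed-form log-normal mean as oracle
  expect_lt(abs(mean(l) / exp(m$loc + m$scale^2 / 2) - 1), 0.02)
  l30 <- sample_fragment_lengths(10, fragment_length_model(min_len = 30),
                                 seed = 4)
  expect_true(all(l30 >= 30))
  expect_error(fragment_length_model(scale = 0), "scale")
})

test_that("damage leaves damage-free inputs untouched", {
  res <- apply_briggs_damage("AAAA", damage_params(), seed = 1)
  expect_identical(res$seq, "AAAA")
  expect_equal(nrow(res$events), 0)
  p0 <- damage_params(ss_deam = 0, ds_deam = 0, nick_rate = 0)
  frag <- generate_reference(60, seed = 5)
  expect_identical(apply_briggs_damage(frag, p0, seed = 2)$seq, frag)
  expect_error(damage_params(ss_deam = 1.2), "\\[0, 1\\]")
})

test_that("terminal deamination matches the analytic mixture rate", {
  params <- damage_params()
  n <- 100000
  frags <- withr::with_seed(42, {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = ""), character(1))
  })
  damaged <- apply_briggs_damage(frags, params, seed = 99)$seq
  first_ref <- substr(frags, 1, 1)
  first_obs <- substr(damaged, 1, 1)
  c_sites <- first_ref == "C"
  rate <- mean(first_obs[c_sites] == "T")
  expected <- briggs_terminal_ct_rate(params)
  se <- sqrt(expected * (1 - expected) / sum(c_sites))
  expect_lt(abs(rate - expected), 3 * se)
  # interior position far from both ends: background + nick rate
  mid_ref <- substr(frags, 20, 20)
  mid_obs <- substr(damaged, 20, 20)
  c_mid <- mid_ref == "C"
  rate_mid <- mean(mid_obs[c_mid] == "T")
  exp_mid <- briggs_interior_ct_rate(params)
  se_mid <- sqrt(exp_mid * (1 - exp_mid) / sum(c_mid))
  expect_lt(abs(rate_mid - exp_mid), 3 * se_mid)
  # 3' terminal G->A mirrors the 5' C->T mixture
  last_ref <- substr(frags, 40, 40)
  last_obs <- substr(damaged, 40, 40)
  g_sites <- last_ref == "G"
  rate_ga <- mean(last_obs[g_sites] == "A")
  exp_ga <- (1 - params$overhang_param) * params$ss_deam
  se_ga <- sqrt(exp_ga * (1 - exp_ga) / sum(g_sites))
  expect_lt(abs(rate_ga - exp_ga), 3 * se_ga)
})

test_that("simulated samples conserve composition and read geometry", {
  fix <- tiny_sim()
  truth <- fix$sim$truth
  expect_equal(sum(truth$n_fragments),
               fix$design$n_ancient_fragments +
                 fix$design$n_modern_fragments)
  expect_equal(sum(truth$n_fragments[truth$is_ancient]),
               fix$design$n_ancient_fragments)
  expect_true(all(truth$n_fragments >= 0))
})

test_that("zero ancient fragments empty the ancient truth counts", {
  sp <- default_species_set(20000L)[c(1, 19), ]
  sp$relative_abundance <- 0.8 * c(0.5, 0.5)
  des <- sample_design("z", n_ancient_fragments = 0L,
                       n_modern_fragments = 500L,
                       microbial_fraction = 0.8, seed = 7L)
  sim <- simulate_sample(des, sp)
  truth <- sim$truth
  expect_true(all(truth$n_fragments[truth$is_ancient] == 0))
  expect_equal(sum(truth$n_fragments), 500)
})

test_that("abundance/microbial-fraction mismatch is rejected", {
  sp <- default_species_set(20000L)[c(1, 19), ]
  sp$relative_abundance <- c(0.5, 0.4)   # sums to 0.9, not 0.8
  des <- sample_design("bad", 100L, 100L, microbial_fraction = 0.8,
                       seed = 1L)
  expect_error(simulate_sample(des, sp), "microbial fraction")
})

test_that("emitted reads have exactly the designed read length", {
  td <- withr::local_tempdir()
  sp <- default_species_set(20000L)[c(1, 19), ]
  sp$relative_abundance <- 0.8 * c(0.5, 0.5)
  des <- sample_design("rl", 300L, 300L, microbial_fraction = 0.8,
                       seed = 21L)
  sim <- simulate_sample(des, sp, out_dir = td)
  r1 <- read_fastq(sim$fastq_r1)
  r2 <- read_fastq(sim$fastq_r2)
  expect_true(all(nchar(r1$seq) == des$read_length))
  expect_true(all(nchar(r2$seq) == des$read_length))
  expect_equal(nrow(r1), 600)
})

test_that("identical design and seed reproduce byte-identical outputs", {
  sp <- default_species_set(20000L)[c(1, 19), ]
  sp$relative_abundance <- 0.8 * c(0.5, 0.5)
  des <- sample_design("det", 200L, 200L, microbial_fraction = 0.8,
                       seed = 33L)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  s1 <- simulate_sample(des, sp, out_dir = td1)
  s2 <- simulate_sample(des, sp, out_dir = td2)
  for (f in c("fastq_r1", "fastq_r2", "truth_tsv", "sam")) {
    expect_identical(unname(tools::md5sum(s1[[f]])),
                     unname(tools::md5sum(s2[[f]])), label = f)
  }
})

test_that("truth SAM coordinates recover fragment origins", {
  # one modern species, no damage pool used, no sequencing errors: every
  # recorded alignment must match the genome substring exactly
  sp <- default_species_set(50000L)[19, , drop = FALSE]
  sp$relative_abundance <- 1
  des <- sample_design("coord", n_ancient_fragments = 0L,
                       n_modern_fragments = 1000L,
                       microbial_fraction = 1, error_rate = 0,
                       seed = 55L)
  sim <- simulate_sample(des, sp)
  g <- sim$genomes[[sp$name]]
  a <- sim$alignments
  expect_equal(nrow(a), 1000)
  recovered <- substring(g, a$pos + 1, a$pos + nchar(a$seq))
  expect_gte(mean(recovered == a$seq), 0.99)
  expect_true(all(a$edit_distance == 0))
})

test_that("damage localizes at fragment ends in ancient reads only", {
  fix <- tiny_sim()
  anc <- fix$sim$alignments[fix$sim$alignments$ref_id ==
                              fix$species$name[1], ]
  mod <- fix$sim$alignments[fix$sim$alignments$ref_id ==
                              fix$species$name[2], ]
  pa <- compute_deamination_profile(anc)
  pm <- compute_deamination_profile(mod)
  expect_gt(pa$p5_ct[1], pa$p5_ct[15])
  # modern reads: terminal and interior rates agree within 3 SE
  se <- sqrt(pm$p5_ct[15] * (1 - pm$p5_ct[15]) / pm$n5_informative[1] +
               1e-12)
  expect_lt(abs(pm$p5_ct[1] - pm$p5_ct[15]), 3 * se + 1e-3)
})

test_that("default study design mirrors the published composition", {
  study <- default_study_design(seed = 2, scale = 0.01)
  expect_length(study$samples, 10)
  fr <- vapply(study$samples,
               function(s) s$design$microbial_fraction, numeric(1))
  expect_equal(fr, c(0.7, 0.7, 0.7, 0.5, 0.5, 0.5, 0.4, 0.3, 0.3, 0.3))
  for (s in study$samples) {
    expect_equal(sum(s$species$relative_abundance),
                 s$design$microbial_fraction)
  }
})
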