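test_that("depth is total aligned bases over reference length", {
  aln <- make_alignments(strrep("A", c(10, 20)), pos = c(0L, 30L))
  expect_equal(compute_depth(aln, 100), 0.3)
  expect_equal(compute_depth(empty_alignments(), 100), 0)
  expect_error(compute_depth(aln, 0), "> 0")
})

test_that("breadth distinguishes stacked from tiled alignments", {
  l <- 25L
  stacked <- make_alignments(rep(strrep("A", l), 4), pos = 0L)
  tiled <- make_alignments(rep(strrep("A", l), 4),
                           pos = c(0L, 25L, 50L, 75L))
  expect_equal(compute_depth(stacked, 100), 1)
  expect_equal(compute_depth(tiled, 100), 1)
  expect_equal(compute_breadth(stacked, 100), 0.25)
  expect_equal(compute_breadth(tiled, 100), 1)
})

test_that("evenness profile bins are consistent with global breadth", {
  set.seed(77)
  for (i in 1:5) {
    ref_length <- sample(500:2000, 1)
    n <- sample(5:60, 1)
    lens <- sample(20:60, n, replace = TRUE)
    pos <- vapply(lens, function(l)
      sample.int(ref_length - l + 1L, 1) - 1L, integer(1))
    aln <- make_alignments(strrep("A", lens), pos = pos)
    prof <- compute_evenness_profile(aln, ref_length, n_bins = 10L)
    expect_equal(sum(prof$bin_sizes), ref_length)
    # global breadth equals the length-weighted mean of bin breadths
    expect_equal(sum(prof$bin_breadth * prof$bin_sizes) / ref_length,
                 prof$breadth)
    expect_equal(prof$depth_mean, sum(lens) / ref_length)
  }
  expect_error(compute_evenness_profile(empty_alignments(), 50, 100),
               "fewer bins")
})

test_that("MD tags recover mismatched reference bases", {
  # read TAAA against reference CAAA: one 5' C->T
  aln <- make_alignments("TAAA", nm = 1L, md = "0C3")
  prof <- compute_deamination_profile(aln, P = 4L)
  expect_equal(prof$p5_ct, c(1, NA, NA, NA))
  expect_equal(prof$n5_informative, c(1L, 0L, 0L, 0L))
  # malformed MD: length disagrees with the sequence
  bad <- make_alignments("TAAA", md = "0C30")
  expect_error(compute_deamination_profile(bad), "disagrees")
  indel <- make_alignments("TAAA", md = "2^AC2")
  expect_error(compute_deamination_profile(indel), "indel")
})

test_that("reverse-strand alignments are flipped into read orientation", {
  # stored (reference-forward) seq TTTA vs ref TTTG: G->A at the right
  # end; in read orientation this is a 5' C->T at position 1
  aln <- make_alignments("TTTA", strand = "-", nm = 1L, md = "3G0")
  prof <- compute_deamination_profile(aln, P = 4L)
  expect_equal(prof$p5_ct[1], 1)
  expect_equal(prof$n5_informative, c(1L, 0L, 0L, 0L))
  expect_true(is_damaged(aln))
})

test_that("damaged-read classification respects the terminal window", {
  # C->T at 5' position 6 is outside the default 5-bp window
  inside <- make_alignments("TAAAAAAAAA", nm = 1L, md = "0C9")
  outside <- make_alignments("AAAAATAAAA", nm = 1L, md = "5C4")
  ga_3p <- make_alignments("TTTTTTTTTT", nm = 1L,
                           md = "0C9", strand = "-")
  # strand '-': oriented read AAAAAAAAAA over ref AAAAAAAAAG has a 3'
  # G->A at position 1 from the 3' end -> damaged
  expect_true(is_damaged(inside))
  expect_false(is_damaged(outside))
  expect_true(is_damaged(outside, terminal_window = 6L))
  expect_true(is_damaged(ga_3p))
  expect_identical(is_damaged(empty_alignments()), logical(0))
})

test_that("edit-distance histograms pool values of 10 or more", {
  aln <- make_alignments(rep(strrep("A", 50), 5),
                         nm = c(0L, 0L, 1L, 10L, 25L))
  h <- edit_distance_histograms(aln, damaged = rep(FALSE, 5))
  expect_equal(sum(h$edit_all), 5)
  expect_equal(unname(h$edit_all[c("0", "1", "10")]), c(2L, 1L, 2L))
  expect_equal(sum(h$edit_damaged), 0)
  h2 <- edit_distance_histograms(aln, damaged = c(TRUE, FALSE, TRUE,
                                                  FALSE, FALSE))
  expect_equal(unname(h2$edit_damaged[c("0", "1")]), c(1L, 1L))
})

test_that("identity histogram bins fixed-length reads correctly", {
  aln <- make_alignments(rep(strrep("A", 50), 5),
                         nm = c(0L, 1L, 2L, 5L, 10L))
  # identities 100, 98, 96, 90, 80
  expect_equal(percent_identity(aln), c(100, 98, 96, 90, 80))
  h <- identity_histogram(aln)
  expect_equal(unname(h), c(1L, 0L, 1L, 3L))
  # below 80% falls outside the histogram
  low <- make_alignments(strrep("A", 50), nm = 11L)
  expect_equal(sum(identity_histogram(low)), 0)
})

test_that("PMD scores match hand-computed log-likelihood ratios", {
  p <- pmd_params()
  # read TAG vs ref CAG: 5' terminal C->T (z=0) plus retained ref-G at
  # the 3' terminal position (z=0)
  aln <- make_alignments("TAG", nm = 1L, md = "0C2")
  expected <- log(p$p_max / p$err) +
    log((1 - p$p_max) / (1 - p$err))
  expect_equal(pmd_score(aln), expected)
  # undamaged read with no informative sites scores exactly 0
  expect_equal(pmd_score(make_alignments("ATTA")), 0)
  # interior retained C at distance z=2 from the 5' end
  aln2 <- make_alignments("AACAA")
  d2 <- p$p_base + (p$p_max - p$p_base) * exp(-p$decay_rate * 2)
  expect_equal(pmd_score(aln2), log((1 - d2) / (1 - p$err)))
  expect_identical(pmd_score(empty_alignments()), numeric(0))
  expect_error(pmd_params(decay_rate = 0), "> 0")
})

test_that("ancient reads separate from modern reads by PMD score", {
  fix <- tiny_sim()
  a <- fix$sim$alignments
  anc <- pmd_score(a[a$ref_id == fix$species$name[1], ])
  mod <- pmd_score(a[a$ref_id == fix$species$name[2], ])
  expect_gt(mean(anc > 3), 0.10)
  expect_lt(mean(mod > 3), 0.02)
})

test_that("assigned-read counting applies a strict MAPQ bound", {
  aln <- make_alignments(rep("ACGT", 4), mapq = c(0L, 1L, 30L, 60L),
                         ref_id = c("a", "a", "a", "b"))
  n <- count_assigned(aln)
  expect_equal(n[["a"]], 2L)   # MAPQ 0 excluded
  expect_equal(n[["b"]], 1L)
  expect_equal(count_assigned(aln, min_mapq = 30L)[["b"]], 1L)
  expect_false("a" %in% names(count_assigned(aln, min_mapq = 30L)))
})

test_that("metrics bundles survive a TSV round trip", {
  fix <- tiny_sim()
  a <- fix$sim$alignments
  anc <- a[a$ref_id == fix$species$name[1], ]
  m <- compute_auth_metrics(anc, 20000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_auth_metrics(m, f)
  back <- read_auth_metrics(f)
  s1 <- score_taxon(m); s2 <- score_taxon(back)
  expect_equal(s2$components, s1$components)
  expect_equal(s2$total, s1$total)
  expect_equal(back$deamination$p5_ct, m$deamination$p5_ct,
               tolerance = 1e-9)
  expect_equal(back$coverage$breadth, m$coverage$breadth,
               tolerance = 1e-9)
  expect_equal(unname(back$edit_all), unname(as.numeric(m$edit_all)))
  expect_equal(back$read_length_median, m$read_length_median)
  expect_equal(back$ani_mean, m$ani_mean, tolerance = 1e-9)
})
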