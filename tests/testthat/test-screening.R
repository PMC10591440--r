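test_that("candidate filtering is inclusive and rank-aware", {
  rows <- data.frame(
    pct = 0, reads = 0,
    taxReads = c(200, 199, 200, 201, 200),
    kmers = c(1000, 1000, 999, 1001, 1000),
    dup = 1, cov = 0, taxID = 1:5,
    rank = c("species", "species", "species", "genus", "species"),
    taxName = paste0("t", 1:5), stringsAsFactors = FALSE)
  kept <- filter_candidates(rows, filter_config())
  # boundary values pass (inclusive >=); genus rank is dropped
  expect_identical(kept$taxName, c("t1", "t5"))
  # order of surviving rows is the input order
  kept2 <- filter_candidates(rows[5:1, ], filter_config())
  expect_identical(kept2$taxName, c("t5", "t1"))
  # wider rank set admits the genus row
  kept3 <- filter_candidates(rows, filter_config(rank_keep =
                                                   c("species", "genus")))
  expect_identical(kept3$taxName, c("t1", "t4", "t5"))
  expect_error(filter_config(min_unique_kmers = -1), ">= 0")
})

test_that("k-mers per read follows L - k + 1", {
  expect_identical(kmers_per_read(50, 31), 20L)
  expect_identical(kmers_per_read(31, 31), 1L)
  expect_identical(kmers_per_read(c(50, 100)), c(20L, 70L))
  expect_error(kmers_per_read(30, 31), "exceed")
  expect_error(kmers_per_read(10, 0), ">= 1")
})

test_that("unique covered k-mers match a brute-force census", {
  ref <- generate_reference(200, seed = 11)
  k <- 5L
  aln <- make_alignments(
    seq = substring(ref, c(1, 4, 100, 150), c(20, 30, 103, 170)),
    pos = c(0L, 3L, 99L, 149L))
  # brute-force oracle: enumerate windows contained in each read span
  windows <- character(0)
  for (i in seq_len(nrow(aln))) {
    span_start <- aln$pos[i] + 1L
    span_end <- aln$pos[i] + nchar(aln$seq[i])
    if (span_end - span_start + 1L >= k) {
      st <- span_start:(span_end - k + 1L)
      windows <- c(windows, substring(ref, st, st + k - 1L))
    }
  }
  expect_identical(count_unique_kmers_covered(aln, ref, k),
                   length(unique(windows)))
  # reads shorter than k contribute nothing
  short <- make_alignments("ACG", pos = 0L)
  expect_identical(count_unique_kmers_covered(short, ref, k), 0L)
  expect_identical(count_unique_kmers_covered(empty_alignments(), ref, k),
                   0L)
  out_of_bounds <- make_alignments(strrep("A", 10), pos = 195L)
  expect_error(count_unique_kmers_covered(out_of_bounds, ref, k),
               "bounds")
})

test_that("repeated reference k-mers are counted once", {
  ref <- strrep("ACGT", 10)  # every 4-mer recurs along the sequence
  aln <- make_alignments(substr(ref, 1, 40), pos = 0L)
  # only 4 distinct 4-mers exist: ACGT, CGTA, GTAC, TACG
  expect_identical(count_unique_kmers_covered(aln, ref, 4L), 4L)
})

test_that("read-length filtering is strict", {
  reads <- data.frame(id = as.character(20:40),
                      seq = strrep("A", 20:40),
                      stringsAsFactors = FALSE)
  kept <- filter_reads_by_length(reads, 31)
  expect_equal(nrow(kept), 9)   # lengths 32..40
  expect_true(all(nchar(kept$seq) > 31))
  expect_error(filter_reads_by_length(reads, -1), ">= 0")
})

test_that("adapter trimming removes the rightmost qualifying match", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "ACGTACGTACGTACGTACGT"
  reads <- data.frame(
    id = c("full", "partial", "short_ov", "none", "twice"),
    seq = c(paste0(insert, adapter, "TTTT"),
            paste0(insert, substr(adapter, 1, 11)),
            paste0(insert, substr(adapter, 1, 5)),
            insert,
            paste0(adapter, insert, adapter)),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  out <- trim_adapter(reads, adapter, min_overlap = 10L)
  expect_identical(out$seq[1], insert)          # interior full match
  expect_identical(out$seq[2], insert)          # 11 bp suffix match
  expect_identical(out$seq[3], reads$seq[3])    # 5 bp < min_overlap: kept
  expect_identical(out$seq[4], insert)          # untouched
  # two matches: rightmost-starting one wins, prefix adapter remains
  expect_identical(out$seq[5], paste0(adapter, insert))
  expect_identical(nchar(out$qual), nchar(out$seq))
  expect_error(trim_adapter(reads, ""), "non-empty")
})
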