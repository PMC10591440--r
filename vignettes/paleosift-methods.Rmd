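---
title: "paleosift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paleosift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosift)
```

This vignette is the package's own account of its models: what is
computed, under which assumptions, with which defaults, and what the
synthetic-data generator does and does not emulate.

# The damage model behind the simulator

Ancient DNA is short, and its cytosines deaminate after death,
read as C→T substitutions concentrated at 5′ fragment ends (and G→A at
3′ ends, the same lesion seen from the complementary strand). The
simulator implements a Briggs-style parametric model
(`damage_params()`):

* **Single-strand overhangs** with geometric lengths: the overhang at
  each fragment end has length $j \ge 0$ with
  $P(j) = p\,(1-p)^j$, $p = 0.4$ (so 60% of ends have an overhang of at
  least one base). Cytosines in an overhang deaminate with probability
  `ss_deam` $= 0.3$ (5′ C→T) and guanines in the complementary 3′
  overhang with the same probability (3′ G→A).
* **Double-strand interior deamination** at `ds_deam` $= 0.01$ per
  interior C.
* **Nicks** at rate `nick_rate` $= 0.03$, which expose interior
  cytosines to single-strand deamination; the net interior C→T rate is

  $$r_\text{int} = d_s + (1 - d_s)\,\nu\,s_s \approx 0.0189 .$$

  The terminal C→T rate is the overhang mixture

  $$r_\text{term} = (1-p)\,s_s + p\,r_\text{int} \approx 0.1876 ,$$

  since with probability $1-p$ the terminal base sits in an overhang
  (`rgeom` has $P(0)=p$, i.e. overhang length 0). These closed forms are
  *not* used by the simulator — it samples overhangs and per-site events
  directly — which makes them independent oracles: the test suite
  simulates $10^5$ fragments and requires the observed terminal,
  interior and 3′ rates to match the closed forms within three binomial
  standard errors.

**Fragment lengths** are log-normal: ancient fragments use
$\log L \sim \mathcal{N}(3.7424069808,\ 0.2795148843)$ (median
$\approx 42$ bp), floored at 30 bp. The modern (contaminant) pool needs
a length model too; none is prescribed, so the package chooses once
$\log L \sim \mathcal{N}(\log 120,\ 0.3)$ — "moderately fragmented
modern DNA", long enough (median 120 bp) to be cleanly separable from
the ancient pool by the read-length criterion but short enough to be
realistic for degraded modern material. This choice was made before any
test was run and is not tuned.

**Study design.** `default_study_design()` reproduces a ten-sample
simulated study: 18 ancient and 17 modern species (real species names,
synthetic random genomes), microbial fractions
$(0.7, 0.7, 0.7, 0.5, 0.5, 0.5, 0.4, 0.3, 0.3, 0.3)$ with the remainder
of each pool drawn from a host genome, 500,000 ancient plus 500,000
modern fragments per sample, and 125-bp paired-end reads with adapter
read-through (reads shorter than 125 bp are padded with adapter sequence
then random bases) and per-base sequencing error $10^{-3}$. The `scale`
parameter multiplies fragment counts only, never rates, so reduced-scale
runs sample the same processes.

What the generator **emulates**: fragmentation, terminal damage
gradients, adapter read-through, uniform sequencing error, host
background, species abundance structure, and exact ground truth (every
read's origin, damage events, and a truth SAM of gapless alignments).
What it does **not** emulate: real genome sequences (genomes are i.i.d.
random, so cross-mapping between related species — the cause of
real-world false positives — cannot arise), GC bias, PCR duplicates,
indels, quality-score structure, library-preparation chimeras, or
interior G→A from double-strand deamination of the opposite strand (the
model's three signatures are 5′ C→T, 3′ G→A, interior C→T). Passing
tests therefore demonstrate the *statistical machinery* —
filters, metrics and scores recover planted signals at the stated rates —
not classifier robustness against confusable genomes.

# Screening

`filter_candidates()` keeps classifier-report rows at species rank with
`taxReads` ≥ 200 (depth) and unique `kmers` ≥ 1000 (breadth proxy);
both comparisons are inclusive. The k-mer threshold is grounded in the
arithmetic `kmers_per_read()`: a read of length $L$ carries $L-k+1$
k-mers, 20 at $L=50,\ k=31$, so 1000 unique k-mers is what 50
non-overlapping 50-bp reads can at best achieve — a floor on genuinely
distributed evidence. `count_unique_kmers_covered()` computes the
alignment-level analogue (distinct reference k-mer strings fully inside
a read span) used when deriving reports from simulation truth.

Preprocessing: `trim_adapter()` removes an exact adapter-prefix match of
at least 10 bases (the rightmost-starting qualifying match, with
qualities trimmed in lockstep; error-tolerant matching is out of scope),
and `filter_reads_by_length()` keeps reads strictly longer than 31 bp so
that every retained read carries at least one classifier k-mer.

# Authentication metrics

All metrics consume an `alignment_set`: gapless primary alignments with
0-based positions, `NM` edit distances and `MD` tags (read via
Rsamtools). Mismatch identities are recovered from the `MD` tag alone
(`parse_md_ref()`), so no reference sequence is needed at metric time;
reverse-strand records are complemented and flipped into read 5′→3′
orientation first. Indel-containing records are rejected rather than
silently mis-scored.

* **Deamination profile** (`compute_deamination_profile()`): C→T
  frequency at 5′ positions $1..P$ and G→A at 3′ positions, $P = 15$;
  frequencies are `NA` where no informative site was seen, and
  informative-site counts are kept for the score's site floor.
* **Coverage** (`compute_evenness_profile()`): mean depth (total aligned
  bases / genome length), breadth (fraction of positions covered), and
  local breadth in 100 equal bins (the last absorbs the remainder). The
  identity "global breadth = length-weighted mean of bin breadths" is a
  conservation property tested on randomized fixtures.
* **Edit distances**: per-read `NM` histograms over bins 0–10 (≥ 10
  pooled), for all reads and for *damaged* reads — those with a terminal
  C→T (5′) or G→A (3′) within 5 bp of the read end.
* **Read lengths, percent identity**: median length;
  $100\,(L-\text{NM})/L$ per read, histogrammed over
  $[80,85), [85,90), [90,95), [95,100]$.
* **PMD score** (`pmd_score()`): per-read log-likelihood ratio of a
  damage model vs a sequencing-error null. The damage probability decays
  with distance $z$ from the relevant end,
  $D(z) = p_\text{base} + (p_\text{max}-p_\text{base})e^{-\lambda z}$,
  with $\lambda = 0.5$/bp, $p_\text{max} = 0.3$, $p_\text{base} = 0.01$,
  error $10^{-3}$. Reference-C sites are scored against the 5′ distance
  and reference-G sites against the 3′ distance; deaminated bases add
  $\log(D/\varepsilon)$, retained ones $\log\frac{1-D}{1-\varepsilon}$.
  These constants deliberately mirror the simulator's damage defaults so
  that end-to-end parameter recovery is testable; they are a package
  choice, not constants imported from external damage tools.

# The 0–10 score

`score_taxon()` awards points per passing criterion: +1 each for 5′ and
3′ deamination, +2 for evenness of coverage, +1 each for the six other
criteria — total 0–10. The default criteria (`score_criteria()`):

* deamination (per end): terminal rate ≥ 0.05 **and** ≥ 2× the interior
  baseline (mean of positions 8–12) **and** ≥ 10 informative terminal
  sites (guards against single-read artifacts);
* evenness: breadth $/ (1 - e^{-\text{depth}}) \ge 0.8$ — the
  Lander–Waterman expected breadth under random read placement, which
  normalizes breadth for depth — and ≥ 40% of bins nonzero;
* edit distance: histogram mode ≤ 1 and non-increasing over bins 0–3
  allowing one inversion; the damaged-read variant additionally needs
  ≥ 20 damaged reads;
* median read length ≤ 100 bp; ≥ 10% of reads with PMD score > 3;
  ≥ 200 assigned reads; mean identity ≥ 90%.

Missing summaries fail their criterion; every criterion is a pure
predicate on the metrics bundle, so scores are reproducible from the
serialized metrics TSVs alone (`write_auth_metrics()` /
`read_auth_metrics()` round-trip everything the score consumes).

# Benchmarking

`jaccard()` and `f1_score()` compare predicted and true taxon *sets*
(duplicates ignored); both are defined as 1 when both sets are empty
(perfect agreement on "nothing present") and F1 is 0 when precision and
recall are both 0. `threshold_sweep()` applies an inclusive read-count
cutoff per sample and averages across samples. `roc_curve()` groups tied
scores into single ROC points and integrates by the trapezoid rule,
which equals the pairwise concordance estimator (concordant pairs + half
ties over positive×negative pairs) — asserted against an exhaustive
pairwise oracle and against pROC in the tests. Inputs with only one
class are an error, not a silent `NaN`.

In `run_end_to_end()` the ROC is computed over present microbial
(taxon, sample) pairs — ancient as positives, modern as negatives — with
unscored present pairs assigned score 0, so taxa removed by screening
still count against sensitivity.

# Numerical and design choices

* **Inclusive thresholds everywhere** (≥): a row with exactly 200 reads
  and 1000 k-mers survives; a score criterion at its boundary passes.
  The read-length preprocessing filter is the one strict inequality
  (keeps length > 31).
* **Determinism**: all randomness flows through `withr::with_seed`;
  per-sample substreams come from `derive_seed()`, an order-independent
  integer hash, so adding a sample never perturbs another sample's
  reads. Outputs (FASTQ, SAM, TSV, log, PNG) are written through binary
  connections with fixed formatting (`%.10g` for floats) and contain no
  timestamps; two runs of the pipeline with one seed are byte-identical,
  and the test suite asserts this at the file-hash level including
  plots.
* **Metrics are computed on fragment-truth alignments (R1 side)**: mate
  pairs share one fragment, so the second read adds no independent
  damage information; using both would double-count sites.
* **Degenerate inputs**: empty alignment sets yield zero
  depth/breadth, `NA` deamination frequencies, empty score components
  (criteria fail); empty reports parse to empty tables; score matrices
  with no pairs warn and return 0×0.
* **Problem sizes in tests** (chosen as the package's own
  accuracy/runtime trade-off): damage-rate oracles at $10^5$ fragments
  (3-SE bands), module simulations at $8\,000$ fragments, the end-to-end
  ROC at 10 species × 4 samples × 20,000 fragments, determinism at 2
  samples × 4,000 fragments; the full suite runs in ~2.5 minutes.

# Known limitations

* Random genomes make cross-species mis-assignment — the hardest
  real-world failure mode — unobservable; the screening filter is tested
  on its contract, not on confusable genomes.
* Gapless alignments only; indels are rejected, not modeled.
* The in-package classifier stand-in assigns every read to its true
  genome; connecting a real classifier means feeding its report files to
  `read_krakenuniq_report()` and its alignments to `read_sam()`.
* PMD scoring assumes the package's own damage parameterization; scores
  are comparable within a run, not calibrated against external tools.
* The score's criteria are fixed thresholds, not fitted models; they are
  transparent and auditable but inherit the arbitrariness of any
  threshold scheme (all defaults are exposed as parameters).
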