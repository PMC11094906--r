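---
title: "Models and methods behind cas13screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cas13screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13screen)
```

# The experiment this package models

A pooled CRISPR-Cas13d proliferation screen knocks down many transcripts —
here, long noncoding RNAs and protein-coding genes — in parallel. Cells
stably expressing Cas13d are transduced at low multiplicity of infection
with a lentiviral crRNA library (about ten guides per gene, roughly a
thousand cells per guide), grown for three weeks, and the integrated crRNA
cassettes are sequenced at the start and end. Guides targeting a gene whose
knockdown accelerates proliferation become enriched; guides against genes
required for proliferation become depleted. The package covers the
computational spine of such a screen: designing the crRNA library, purging
guides with off-target complementarity, counting guides from reads, checking
count-level quality, calling gene-level hits, and two small downstream
analyses (allele-specific RNA half-life, and RNA pull-down enrichment).

Every input can be generated by the synthetic-data functions
(`simulate_*`), so the whole pipeline can be exercised — and its error
behaviour measured against known ground truth — without any external data.

# Guide selection

`design_library()` implements a staged selection per transcript, given
candidate guides scored by an upstream quality model (scores are inputs; the
scoring model itself is out of scope):

1. **Strict stage.** Only candidates in the top quartile of that
   transcript's scores are considered. A greedy pass in order of
   (score descending, start ascending, sequence) accepts a candidate iff its
   target window does not overlap any already-accepted window, stopping at
   `target_per_transcript` (default 10).
2. **Quartile relaxation.** If fewer than `min_guides` (default 5) survive,
   the greedy pass is repeated admitting candidates down to the third
   quartile, still with zero overlap.
3. **Overlap relaxation.** If still short, the pass is repeated tolerating
   pairwise overlaps up to `relax_overlap_max_nt` (default 10 nt, reading
   the tolerated "5–10 nucleotide overlap" band as its upper bound).

The first stage reaching `min_guides` wins; transcripts that never reach it
keep whatever the final stage found (at least one guide) and carry a
`below_minimum` flag — in realistic libraries a few percent of genes can
only field 2–9 guides that pass quality control. Quartiles are computed per transcript (the
upstream scorer's convention) with linear-interpolation percentiles and ties
resolving upward, so degenerate score sets (fewer than four candidates, or
all equal) default to the top quartile rather than discarding a transcript.

The greedy order is a total order: score, then start, then sequence. A
"top ten guides" rule alone does not fix an order among ties; a total
tie-break is required for the selection to be a pure function of the
candidate set, which the tests assert by permuting input rows. Redundancy removal collapses exact
duplicate spacers within a gene and deletes spacers shared by two genes
(they cannot be attributed). The spacer column stores the target-site
(protospacer) sequence; a config switch emits the reverse-complement crRNA
orientation instead, since published library tables differ in convention.
Flanking sequences for synthesis are config-supplied and default to empty —
the real cloning flanks are vector-specific.

# Off-target scanning

A guide is considered off-target when a contiguous substring covering at
least 90% of it (≥ 21 nt of a 23-mer, `ceiling(0.9 × L)`) matches a
reference window outside the guide's own gene with at most two mismatches.
Matching is ungapped Hamming matching in target-site space: "coverage" (a
BLAST-style alignment-summary notion) is operationalized as contiguous
placements, since a gapped RNA:RNA duplex with
Cas13d is not a modelled quantity. Ambiguity codes in references count as
mismatches. For genomic references both strands are scanned; for a
transcriptome only the sense strand (Cas13d binds the transcript).

Two independent implementations are exported:

* `scan_offtargets()` — the production scanner. By the pigeonhole
  principle, any qualifying placement (length ≥ 21, ≤ 2 mismatches)
  contains an exact run of at least `floor(21/3) = 7` matching bases, so
  exact 7-mer seeds against a reference index find every candidate
  diagonal, and each diagonal is verified by explicit Hamming counting.
* `brute_force_scan()` — the oracle: an exhaustive enumeration of every
  (guide substring, reference window, strand) placement. The test suite
  asserts exact hit-set equality between the two on hundreds of randomized
  instances with planted mutated copies, and validates the oracle itself
  against a small pure-R enumeration.

Nested placements at one locus collapse to the longest, then
fewest-mismatch placement. The locus anchor is the guide's 5′ end
(`ref_start` on "+", alignment end on "−"); anchoring on the raw reference
start would make hit sets asymmetric under reverse-complementing the
reference, which the suite checks as an invariant. `filter_library()`
removes every guide with at least one hit and reports each removal with its
worst hit.

# Counting and quality control

`count_reads()` anchors on the first exact occurrence of the 5′ flank in
each read, extracts the following spacer-length bases, and requires an exact
spacer match — no mismatch rescue, so sequencing errors reduce the match
rate rather than inflating counts. Reads are conserved by construction:
assigned plus discarded (no flank / truncated / unknown spacer) equals
total, and `simulate_fastq()` followed by `count_reads()` reproduces its
input counts exactly.

Quality control uses the two statistics screeners actually look at:

* **Gini index** of each sample's guide counts,
  `G = (2 Σ i·x₍ᵢ₎)/(n Σx) − (n+1)/n` with counts sorted ascending — 0 for
  perfectly even counts; an even, un-bottlenecked screen stays below 0.1.
* **Pairwise replicate Pearson correlation** on `log2(count + 1)`; healthy
  replicates exceed 0.9. The log transform is the package's choice (the
  convention underlying published correlation figures is rarely stated);
  a pseudocount of 1 is used wherever logs of counts are taken.

`median_ratio_normalize()` is the standard median-of-ratios size-factor
estimator, with factors rescaled to geometric mean 1. The rescaling makes
normalization exactly idempotent; without it, re-estimated factors equal the
geometric mean of the original per-sample medians rather than 1 (medians are
not multiplicative, so the naive "median ratio = 1 after normalization"
identity holds only approximately for any scaling).

# Hit calling

The gene test is a deliberately simplified implementation of the
negative-binomial + rank-aggregation scheme that is standard for pooled
screens (the MAGeCK family); byte-equivalence with any particular release
of those tools is not a goal — calibration is established by simulation instead.

1. **Mean–variance model.** On normalized baseline replicates,
   overdispersion is modelled as `σ²(μ) = μ + exp(a)·μᵇ`, with `(a, b)`
   from least squares of `log(max(s² − μ̂, 0.01))` on `log μ̂` over guides
   with positive mean. The 0.01 clamp keeps Poisson-like guides (where
   `s² − μ̂` is near or below zero) from producing undefined logs; for pure
   Poisson data the fitted correction term becomes negligible.
2. **Guide tails.** For each guide, the summed treatment counts are
   compared with a negative binomial with mean `n_treat·μ` and variance
   `n_treat·σ²(μ)` (Poisson if the model variance does not exceed the
   mean). Both tails include the observation (`p_high = P(X ≥ x)`,
   `p_low = P(X ≤ x)`), and tails are floored at the smallest positive
   double so p-values stay in (0, 1] even for extreme guides. Guides with
   zero baseline mean are excluded and reported.
3. **α-RRA.** Guides are ranked per direction by (p-value, crRNA id) — a
   stable total order — and normalized to ρ = rank/m. A gene with guides at
   sorted ρ₍₁₎ ≤ … inside the top α fraction (default α = 0.25) scores
   `min_j BetaCDF(ρ₍ⱼ₎; j, n_g − j + 1)`: the probability that the j-th of
   n_g uniform order statistics falls that low. Genes with no guide inside
   α score 1.
4. **Permutation p-values.** For each guide-count class, gene scores are
   recomputed on ranks drawn without replacement from the observed rank
   pool (`n_perm` = 10,000 by default), with the add-one estimator
   `(1 + #[perm ≤ obs])/(n_perm + 1)`, so the smallest attainable p is
   `1/(n_perm + 1)`.
5. **FDR and classification.** Benjamini–Hochberg per direction; a gene is
   a positive (proliferation-promoting knockdown) or negative hit at
   FDR ≤ 0.3, the screen's high-confidence threshold. If both directions
   pass, the smaller permutation p wins and the gene is flagged ambiguous.
   Guide-level flags ("differentially represented": |lfc| > 0.1 and tail
   p < 0.05) reproduce the screen's scatterplot colouring.

`rerun_after_filter()` repeats the whole analysis after off-target removals
and reports genes whose classification changed — the workflow screens
actually follow, where some initial hits do not survive library filtering.

Treatment replicates are summed for the tail test and the baseline is the
common day-0 pool (unpaired), matching the simulator's design. Gene log2
fold-change is the median guide lfc.

# Downstream statistics

**RNA half-life.** `fit_decay()` regresses `ln(abundance)` on time with a
free intercept — the series are normalized to a control transcript upstream,
and the free intercept absorbs any residual scale, which the tests confirm
by rescaling invariance. Then `k = −slope` and `t½ = ln 2 / k`; slopes ≥ 0
are flagged non-decaying with infinite half-life rather than a negative one.
The default simulated design is the experiment's: harvests at 0, 3, 4, 8,
12 h, protective allele t½ = 11 h, risk allele 6 h (ratio 6/11 ≈ 0.545).
At five timepoints with log-normal noise of sd 0.1 the slope's standard
error is ~0.011/h, so half-life recovery to ~10% relative error is the
realistic expectation the property tests assert for the default allele pair.

**Pull-down enrichment.** `rank_pulldown()` applies a two-sided one-sample
t-test of the five replicate log2 ratios against 0 per protein, then the
standard reporting conjunction — at least 5 identified peptides, mean log2
fold-change > 2 over the control capture, p < 0.05 — and ranks passers by
mean fold-change. The one-sample form is the package's reading of a "t-test
for summed abundance based ratios"; a paired test against the control
channel would require per-channel abundances the ratio table no longer
contains. Zero-variance replicate sets (identical ratios) are reported at
the machine floor with a flag instead of p = 0.

# The synthetic-data generator

`simulate_screen()` draws, per guide, a baseline log-abundance
`aᵢ ~ Normal(0, sigma_lib²)` and an efficacy `uᵢ ~ Beta(5, 2)` (mean ~0.71
— most designed guides knock down well, a minority are weak; no efficacy
distribution is published, so this is the package's modelling choice). Each
non-control gene is positive, negative, or null with configured fractions
and a signed total effect δ (default |δ| = 2), so a guide's realized log2
fold-change is `uᵢ·δ_g`. Sample counts are multinomial draws at the
configured depth over proportions `∝ exp(aᵢ)` (baseline) or
`∝ exp(aᵢ)·2^(uᵢ·δ_g)` (final); replicates share the truth and differ only
in sequencing sampling.

What this emulates — and what it does not:

* **Library unevenness** is log-normal with sd `sigma_lib = 0.15`. Healthy
  screens report only that their Gini index stays below 0.1; 0.15 is the
  dispersion consistent with that bound at full sequencing depth, not a
  measured value.
* **Sequencing** is multinomial: no PCR jackpotting, no sequencing error,
  no index hopping. Match rates from `count_reads()` on simulated FASTQ
  are therefore 1 by construction.
* **Replicates** share the baseline abundances; real biological replicates
  are independent transductions. Shared truth keeps recovery measurable.
* **Cell-level stochasticity is not modelled.** The `coverage`
  (cells-per-guide) parameter is recorded and validated but adds no
  variance layer; growth is deterministic given efficacy and effect. Power
  estimates from this generator are accordingly optimistic upper bounds
  for real screens.
* **Scale.** The defaults are a desk-scale profile (200 genes × 10 guides,
  depth 2×10⁵ — a 1:100 scale-down of 20 M reads/replicate that keeps
  ~100 reads per guide). One consequence worth knowing: at ~100 reads per
  guide, multinomial noise (per-guide log-variance ≈ 1/μ ≈ 0.009) is of
  the same order as the shared library signal (σ² ≈ 0.023), which caps
  attainable replicate correlation near
  σ²/(σ² + 1/μ) ≈ 0.71. The >0.9 correlation a real screen shows emerges
  only at full depth (~1100 reads/guide), where the same generator yields
  r ≈ 0.96 — the QC acceptance test therefore runs at the full-scale
  18,248-guide, 20 M-read geometry (a few seconds of compute), while
  hit-calling power and calibration tests use the desk scale.

`simulate_library_manifest()` is a synthetic stand-in for a full-scale
library table: 1,864 target genes plus 20 chromosome-Y control genes,
18,248 crRNAs, with ~5% of target genes holding 2–9 guides. Its spacers are
random; only the bookkeeping shape is meaningful.

The decay and pull-down generators are direct draws from the models their
fitters assume (exponential decay with log-normal noise; normal log2
ratios), which makes their recovery tests exact calibration checks rather
than robustness studies.

All generators draw inside `withr::with_seed()`: outputs are bit-reproducible
functions of (parameters, seed) and the caller's RNG state is untouched.

# Numerical and design notes

* Coordinates are 0-based half-open throughout (BED convention).
* Guide ranks use stable sorts with crRNA id as final tie-break; rerunning
  with a fixed seed reproduces result tables byte-identically.
* `bh_adjust()` delegates to `stats::p.adjust(method = "BH")`.
* The permutation pool for gene p-values is the full set of observed
  normalized ranks, so p-values are calibrated against the realized rank
  distribution, not an idealized uniform.
* Problem sizes in the test suite: off-target oracle equivalence runs 200
  instances of 100 guides against 50 kb of reference; null calibration uses
  500 genes × 10 guides; power uses 200 genes with 10% positives and 10%
  negatives at coverage 300 and depth 2×10⁵. These sizes make the whole
  suite run in a couple of minutes while keeping binomial confidence
  intervals tight enough for the asserted bounds.

# Known limitations

* Off-target matching is ungapped; bulged RNA:RNA duplexes are invisible.
* The scanner's contract is correctness at the tens-of-megabases scale, not
  genome-scale throughput engineering.
* The NB test assumes the mean–variance trend fitted on baseline replicates
  transfers to treatment; copy-number effects, paired designs, and
  MLE-based effect-size estimation are out of scope.
* Allelic read deconvolution for the half-life assay happens upstream; the
  fitter consumes per-allele series.
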