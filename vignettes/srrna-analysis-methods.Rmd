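---
title: "Methods: srRNA target discovery and its statistical validation"
author: "srrnascout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: srRNA target discovery and its statistical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

Small rDNA-derived RNAs (srRNAs) are short (19–50 nt) RNAs whose sequences
match the ribosomal DNA repeat unit. Because diverged copies of rDNA
segments are scattered through the genome, an srRNA read can align both to
the rDNA unit and to one of these genomic remnants. The analysis proceeds
in two strict passes: reads are first quality-trimmed and aligned to the
rDNA unit — only reads with an rDNA alignment (the srRNA class) continue —
and those reads are then aligned to the genome. Genome placements are
grouped into per-mapping records (one per distinct chromosome, start, end,
strand and aligned sequence), merged into regions (maximal runs of
overlapping or bookended mappings), and assigned to every annotated gene
they overlap by at least 1 bp, strand-agnostically. The gene set so obtained
is the set of srRNA target genes.

Around the targets, three context analyses run: (i) z-scored metaprofiles of
genomic signal tracks in 10-bp bins across ±1.5 kb windows centred on
mapping midpoints; (ii) the base-pair-weighted composition of a 15-state
chromatin segmentation at targets versus the whole genome, with a per-state
unequal-variances (Welch) t-test; (iii) classification of expressed TSSs
into bidirectional (divergent pairs on opposite strands, less than 1 kb
apart, transcripts running apart) and unidirectional promoters, after
removal of minor TSSs expressed below 1% of their gene's strongest TSS
(strict inequality).

Validation rests on two resampling constructions. The *permutation null*
shuffles the order of every read's bases — each base travelling with its
quality score, so per-read composition and quality profiles are conserved
exactly — and reruns the entire pipeline; mapped-read counts, region
intersections, interval Jaccard statistics, target-gene overlaps with their
hypergeometric tail probabilities, and a rank correlation of binned
coverage quantify how completely the mapping signal collapses. The
*Monte-Carlo calibrations* check that the two-sided Mann–Whitney U-test
holds its nominal type-I error on expression-shaped (zero-inflated,
heavy-tailed) data: repeatedly drawing two disjoint 1,575-value subsets
from a shuffled 60,522-value vector (or one subset against the full
vector) and counting rejections at α = 0.05 over 10,000 repetitions.

# The synthetic study and what it emulates

Everything is exercised on generated data with known truth. The default
scale is 1/10 of the real system so a full run takes seconds: a 4,300-bp
rDNA unit whose segments keep the real unit's proportions (the intergenic
spacer takes ~69%, 28S is the longest transcribed segment), a 1.2-Mb genome
over three chromosomes carrying 60 multi-exon genes, 45 planted rDNA
fragments, and 50,000 reads. Scale, counts and rates are all configurable
(`default_study_config()`).

Reads start inside weighted *hotspots* of the unit: ten main peaks (one in
18S, a prominent one at 5.8S, five in 28S with the strongest at the 5′
region of 28S, small ones in the spacers) plus ~13 low-weight minor source
regions spread across the transcribed portion — the real unit sources
srRNAs from thousands of regions, not only the main peaks. Read lengths
follow a discretised two-component truncated normal on [19, 50]: a narrow
component at 25.5 ± 2 nt reproduces the observed twin peak at 25/26 nt, and
a broad component is centred so the overall mean is 29 nt. 99.5% of reads
are sense-strand; antisense reads source from intergenic-spacer hotspots.
Qualities sit on a Q38–40 plateau with optional short low-quality tails
(probability 0.2 per end, ≤ 3 nt, Q8–17) so that trimming has work to do,
and bases carry a 0.003 per-base substitution error rate — error-free reads
would be unrealistic and would make near-identical planted copies
indistinguishable to a best-locus aligner.

Planted fragments copy a source interval of the unit, diverge it by
substitution only (no indels; the downstream aligner is gapless), and are
inserted into introns (80%) or intergenic space (20%), reverse-complemented
with probability 0.3. Three generator design choices deserve explanation:

* **Hotspot dealing and partitioning.** Fragments draw their source regions
  from hotspots round-robin, and a hotspot dealt to several fragments is
  partitioned into per-fragment sub-intervals (each source covers its
  sub-interval plus the 50-nt maximum read length, with at most 20 bp of
  extra padding). Without this, several near-identical copies of one
  popular region compete for the same reads, and best-locus reporting with
  a deterministic tie-break can starve some copies of all hits — the
  partition guarantees each fragment a private pool of read windows.
* **Stratified substitutions.** Divergence places one substitution per
  block of `round(1/(1 - identity))` bp (~27 bp at the default 96.32%
  identity) at a random in-block position. The realized substitution rate
  is exact, and substitutions cannot cluster locally, so every part of a
  planted copy remains reachable by mismatch-capped alignment. Real
  substitution spacing is closer to Poisson; the stratified choice trades
  that realism for controlled, testable recovery behaviour.
* **Truth records.** The generator logs each read's origin interval and
  strand and each fragment's source, orientation and host gene; the true
  target-gene set is the set of host genes of hotspot-sourced fragments.
  Recovery tests score sensitivity and precision against it.

What the generator does **not** emulate: hairpin secondary structure and
Microprocessor cleavage preferences, repeat families other than the planted
rDNA remnants, indel divergence, chimeric rearrangements, GC or positional
sequencing biases, and raw RNA-seq/4C read generation (expression tables
and signal tracks are generated directly). Passing tests therefore show the
pipeline's logic is correct under the stated generative model, not that the
biological claims hold on real accessions.

# The aligner

The aligner is gapless and end-to-end: candidate loci come from exact
matches of every overlapping k-mer (default k = 12) of the read and of its
reverse complement against a hash index of the reference; each candidate is
scored by Hamming distance with `N` mismatching everything; the minimum-
mismatch locus within the cap is reported with its multiplicity (number of
equally-best loci). Ties break deterministically to the lowest (target
name, start), `+` strand before `-`.

With m mismatches a read splits into m + 1 clean runs, so a clean k-mer
window — and hence full sensitivity — is guaranteed only when the read
length is at least (m + 1)(k − 1) + m + 1, i.e. 36 nt at k = 12, m = 2.
Shorter reads carrying the full mismatch budget can be missed; this is a
documented limitation for the 19–35-nt part of the length range, and the
oracle-equivalence tests draw reads of length ≥ 36 where exact agreement
with a brute-force scan over every position and strand is provable.

The two passes use different mismatch caps: 2 for the short rDNA pass
(maximum sensitivity in selecting the srRNA class) and 1 for the genome
pass. The genome pass is deliberately stricter: an a-priori calculation at
the default scale (1.2 Mb of random genome, ~50k reads, the default length
mixture) puts the expected number of chance alignments of short reads at
cap 2 near five — enough to contaminate the target-gene set — while cap 1
brings it well below one. Both caps are configurable per pass.

# Statistical components and numerical choices

* **Hypergeometric overlap.** `hypergeom_overlap_p(q, m, N, k)` returns the
  strict upper tail P(X > q) by log-space summation of `lchoose` terms with
  a max-shift, stable for the study-sized call (N = 60,522). It agrees with
  term-by-term enumeration on all small configurations and with the
  distribution function in R.
* **Mann–Whitney U.** U is computed from midranks. For small tie-free
  samples (n1 + n2 ≤ 12) the exact null distribution is used; otherwise the
  normal approximation with tie-corrected variance and a 0.5 continuity
  correction. A zero variance (all values identical) returns p = 1. The
  full-vs-subset Monte-Carlo loop avoids re-ranking the 62,097-value
  combined sample each repetition: the subset is a subsample of the fixed
  full vector, so combined midranks and tie corrections are reconstructed
  from a precomputed order structure of the full vector in O(subset log
  subset) per repetition; the unit tests assert this path equals the direct
  computation to 1e-12.
* **Calibration design.** The two equal subsets are disjoint by
  construction (drawn without replacement from one shuffle). "Type-I error
  rate" here is the empirical rejection fraction under a constructed true
  null at strict `p < alpha`. Default problem sizes are the study's own:
  60,522 values, subsets of 1,575, 10,000 repetitions.
* **Read shuffling.** The permutation draws a uniformly random permutation
  per read via R's `sample.int` (Fisher–Yates-equivalent by construction)
  and applies it to (base, quality) pairs; conservation of the pair multiset
  is asserted on every trial in the test suite.
* **Correlation under permutation.** The observed-vs-permuted coverage
  correlation is Spearman's rank correlation on counts binned at 1 kb, with
  z = rho * sqrt(n_bins − 1) and a two-sided normal p. A constant vector
  (the typical permuted outcome: all-zero coverage) yields z = 0, p = 1 by
  convention. This replaces the external correlation tool used in the
  original workflow; only the contract — no significant correlation under
  permutation — is preserved.
* **Metaprofiles.** Bin values are length-weighted means of track steps;
  uncovered positions count as zero. Windows running off a chromosome end
  are clipped with per-bin denominators adjusted, and bins entirely out of
  bounds are excluded. Z-scoring subtracts the bin-vector mean and divides
  by its SD; an SD of zero (constant track) returns an all-zero profile
  rather than an error, since constant tracks are legitimate fixtures.
  Metaprofiles are linear in the track before z-scoring and invariant to
  positive affine track transforms after it.
* **State composition and test.** Composition is base-pair-weighted (not
  mapping-count-weighted), with targets merged first so overlapping records
  are not double counted and untiled base pairs reported as an
  `unannotated` bucket; both fraction columns sum to 1 within 1e-9. The
  Welch test's replication unit is the chromosome — the only replication
  available without biological replicates; chromosomes with no target base
  pairs are dropped, at least two are required, and a degenerate
  zero-variance comparison returns t = 0, p = 1 (equal means) or p = 0.
  No multiplicity correction is applied across states.
* **TSS rules.** "Transcription should not intersect" is implemented as
  divergent orientation: the `-` strand TSS must lie at or left of the `+`
  strand TSS. Convergent or tandem pairs within 1 kb are unidirectional.
  The minor-TSS threshold is a strict `<` at 1% of the gene's maximum.
* **Coordinates.** All internal coordinates are 0-based half-open; GFF3 is
  converted at the boundary (1-based inclusive), BED/bedGraph are native.
  Mapping-record midpoints use `floor((start + end) / 2)`.
* **Determinism.** Every stochastic operation takes a seed; the
  orchestrator derives per-stage seeds from one master seed by a fixed
  affine map, so identical (config, seed) pairs give bit-identical
  scientific outputs and individual stages can be rerun in isolation.

# Orchestration

`validate_config()` accepts YAML (path or text) or a list, fills defaults
(trimming 18/18/4:22/20, flank 1,500 bp, bin 10 bp, minor-TSS 1%,
bidirectional distance 1,000 bp), rejects unknown keys, and validates
thresholds with errors naming the offending key. `run_all()` executes
simulate → qc → rDNA pass → genome pass → targets → epigenomics →
validation in fixed order, records per-stage counts, seeds and wall times
in a JSON manifest (written even on stage failure, with the failing stage
named), and skips validation stages cleanly when their repetition counts
are zero. The package's interface is its functions; the orchestrator is the
single entry point for end-to-end runs.

# Problem sizes used by the tests

Unit tests run the pipeline on a reduced study (3 × 100-kb chromosomes,
15 genes, 12 fragments, 4,000 reads); the acceptance-level checks use the
full default scale (1.2-Mb genome, 45 fragments, 50,000 reads, ten
permutation trials) and the full calibration sizes (60,522 values, 1,575
subsets, 10,000 repetitions). These sizes are the package's defaults for a
complete desk run.

# Known limitations

* Real-data results that depend on the original sequencing accessions
  (absolute read, region and gene counts; the expression-shift p-values)
  are out of scope; the package validates the machinery, not the
  biological dataset.
* The aligner's sensitivity guarantee does not cover the shortest reads at
  the full mismatch budget (see above); presets of read aligners used in
  the original workflow are approximated by per-pass mismatch caps.
* The per-mapping "coverage" column is implemented as the depth of
  identical placements (`mean_depth = read_count`), one reading of an
  underspecified field.
* Antisense srRNA generation (intergenic-spacer hotspots) is a plumbing
  placeholder: the generative process of real antisense srRNAs is unknown,
  so only their rate and location are emulated.
* The Welch test's per-chromosome replication is an interpretation; with
  three default chromosomes its power is minimal, and it is exercised for
  correctness, not inference.
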