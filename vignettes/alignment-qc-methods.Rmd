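---
title: "Mismatch-centric alignment QC: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mismatch-centric alignment QC: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnqc)
```

# The problem

Short-read sequencing errors are not random. Library chemistry leaves
strand-asymmetric fingerprints (oxidative damage converts G to T on the
damaged strand, so C>A and G>T mismatch proportions — which should be equal
under strand-symmetric noise — drift apart; formalin fixation inflates
C>T/G>A), cluster phasing and pre-phasing concentrate errors and quality
loss at read ends, and instrument- or run-level faults produce sharp spikes
at individual sequencing cycles, sometimes confined to one member of the
read pair, one strand and one flanking sequence context. Standard
alignment-QC tools summarise mapping quality, insert size and base quality
but do not dissect base mismatches against the reference, which is where
these signatures live. `alnqc` re-walks every aligned read against the
reference genome and accumulates mismatch-centric profiles fine enough to
expose them, then layers multi-sample outlier detection, depth profiling,
site interrogation, discordant-pair extraction and a logistic
site-confidence model on top.

# The core accumulation model

A *substitution* is a read base that differs from the reference base at its
aligned position. Reads are re-aligned from their CIGAR, contig and
coordinate; every M/=/X base is compared with the reference. For each
mismatch we record:

* **cycle** — position in sequencing order. For reverse-strand alignments
  the stored bases run 3'→5' relative to sequencing, so query index $i$
  (0-based) maps to cycle $L - i$ instead of $i + 1$.
* **category** — one of the 12 ordered `ref>read` pairs, kept in reference
  (genome forward strand) orientation. We deliberately do not collapse
  complementary categories or re-orient by strand: strand-asymmetric
  artifacts are only visible if C>A and G>T (for example) are tallied
  separately, stratified by the four orientation classes R1F/R1R/R2F/R2R
  (first/second in pair × forward/reverse strand).
* **flanking context** — the reference bases immediately 5' and 3' of the
  site on the genome forward strand (16 duplets, written e.g. `G_G`).
  Mismatches at contig ends lack a flank and are excluded from context
  tallies only.
* **base quality**, binned at {0–10, 11–20, 21–30, ≥31}. The lowest bin
  edge matches the conventional "low quality (≤10)" cut-off used when
  describing artifact-enriched mismatches.

Three feature families summarise the stream: the **per-cycle profile**
(substitution rate per cycle = 100 × mismatches / reads with an aligned
base at that cycle, mean mismatch quality per cycle, and each cycle's
category spectrum), the **substitution-category profile** (overall spectrum
with quality bins and per-category context distributions), and
**read-mismatch-content** (the histogram of per-read mismatch counts,
binned 0–4 and ≥5, with the full raw table logged). Everything is kept per
orientation class, with the overall stratum as their sum, so the
conservation identities — per-cycle totals = category totals = Σ k·rmc(k),
and R1F+R1R+R2F+R2R = overall — hold exactly and are asserted in the tests.

Positions where either base is `N` are never substitutions; they are
excluded from the per-cycle denominators and counted separately. Mismatch
determination is against the reference FASTA, never the MD tag; MD tags
(recomputed independently with `samtools calmd`) serve as a test oracle
only.

## Denominator and filter choices

The per-cycle denominator is the number of kept reads with an aligned
(M/=/X), non-N base at that cycle — soft-clipped and inserted cycles do not
contribute. The default record filter keeps mapped, primary,
non-supplementary, non-duplicate, non-QC-failed paired reads; each switch
is exposed (`filter_policy()`), and skipped categories still feed the
summary counters. The tool is paired-end only: unpaired records are
rejected from orientation classification by design.

Other defaults worth knowing: insert sizes use |TLEN| of read 1 of proper
pairs only (avoiding double counting), capped at 2000 bp with an overflow
bucket; mean depth is total aligned bases / reference (or region) length;
adapter content is exact-prefix matching of a configurable adapter list
against 3' soft-clipped tails (≥5 bp overlap); the overall error rate is
reported both per aligned base and per read, since either normalisation is
defensible. Hard clips count toward clip-length distributions but consume
no cycles.

# Multi-sample comparison and outlier detection

Per-sample QC logs become an M × N matrix — M samples by N feature bins,
each cell the proportion (percent) of the sample's reads or mismatches in
that bin — so library-size differences do not dominate distances. Samples
are clustered on Euclidean distances with Ward linkage (`ward.D2`, the
squared-increase form of the Ward objective, which is the convention that
actually minimises within-cluster variance on Euclidean input).

The **pair-deviation metric** drives outlier detection: for the six
complement pairs (C>A:G>T, C>T:G>A, C>G:G>C, A>T:T>A, A>G:T>C, A>C:T>G) we
take the signed difference of the two categories' percentages. Under
strand-symmetric errors every deviation is ~0; oxidative damage pushes
C>A:G>T away from zero. Clustering operates on these six deviations.

**Dixon's Q** flags single outliers in small samples (3 ≤ n ≤ 30), using
the ratio variant conventional for the sample size (r10 up to n=7, r11 to
10, r21 to 13, r22 beyond) and two-sided critical values. The constant
table covers α ∈ {0.10, 0.05, 0.02, 0.01, 0.005, 0.002}; the default
α = 0.002 matches the reporting threshold used throughout for cycle and
context outliers. Because published tables stop short of α = 0.002, the
embedded table was calibrated once by Monte Carlo (2×10⁶ null normal
samples per n) and checked against the classical published r10 values at
the levels where they exist (agreement within 0.001); it is frozen as a
package constant, so no randomness occurs at test time. **Cycle-spike
detection** runs Dixon on each cycle's rate against its ±10-cycle window
(a second pass removes already-flagged cycles from neighbouring windows so
adjacent spikes cannot mask each other). The window default is a design
choice — "adjacent cycles" is not otherwise defined — and is configurable.
A consequence worth knowing: a spike riding on a steep local trend is
genuinely not a Dixon outlier against its window; the test is sharpest
where the local profile is flat.

# Depth, sites, discordant pairs

`genedepth` builds per-position pileups (via `Rsamtools::pileup`) for
exon-wise BED intervals: depth counts aligned bases only and splits into
reference-matching and non-reference bases (they sum to depth by
construction); deletion-spanning reads are tallied separately. Interval
summaries give length, reference GC%, mean depth and fraction of positions
covered at {1, 10, 20, 30, 50, 100}× — a threshold set covering the 10×
and 30× analyses a practitioner typically quotes — and zero-coverage exons
are flagged prominently. `siteinfo` lists every kept read over a queried
coordinate (base, quality, strand, pair member, mapping quality, template
length, read group) with per-allele aggregates; deletion-spanning reads are
listed but excluded from depth and allele counts. `jumpreads` classifies
pairs with precedence INTERCHROM > orientation anomaly (FF, RR, outward) >
long insert (default ≥1000 bp) > normal, so each read gets exactly one
class, and writes selected records to a BAM. Pair closure holds because
both mates of a pair satisfy the same symmetric predicate.

# The site-confidence model

At candidate variant sites we aggregate read-level features: mean/median
per-read mismatch count, fraction of clipped reads, mean per-read indel
count, mean and fraction-zero mapping quality, mean |insert|, and two
homopolymer lengths measured on the reference — the maximal run of the
reference base containing the site, and the longest adjacent run of the
alternate base. The homopolymer definitions are interpretive (several
readings are defensible); both runs are recorded so users can substitute
their own. A plain maximum-likelihood logistic regression (no
regularisation; L2 via `glmnet` would be a trivial extension but changes
the estimand) is fit on a seeded stratified 70/30 split, with test accuracy
reported separately for heterozygous and homozygous-alternate site classes.
The headline accuracies reported for real benchmark-vs-novel site sets
(~81.5% het, ~72.7% hom-alt) require hundreds of gigabytes of consortium
data and are not reproduced here; instead the package validates the
machinery on synthetic data where truth is computable: coefficients of a
known generating model are recovered within ±10% at n = 20 000, and
classes built from unit-variance Gaussians separated by d = 2·Φ⁻¹(0.8)
(Bayes accuracy exactly 80%) yield held-out accuracy of 80 ± 3.

# The fixture generator

Every analysis is testable without downloads because the package ships a
seeded generator that writes a reference FASTA and a coordinate-sorted,
indexed BAM of *pre-aligned* reads: true positions are known and CIGARs are
constructed from the injected events, so truth tables are exact rather than
approximated through an external aligner. Injection rules plant
substitutions by category, rate, cycle set, orientation class and flanking
context (e.g. `GAG → GGG` only in second-in-pair forward reads at four
fixed cycles), with error-base qualities drawn low (mean Q12 vs Q32 for
correct bases) so quality-bin assertions have truth values. Indel,
soft-clip, pile-up ("trap region") and atypical-pair rules (long-insert,
inter-chromosomal, FF/RR/outward) cover the remaining modules. Determinism
is absolute: identical spec + seed gives byte-identical SAM streams and
truth tables.

What the generator does *not* emulate: mapping ambiguity (positions are
true by construction, so mapping-quality pathology must be injected, not
emergent), PCR duplicates, overlapping-mate double counting, reference
bias, and realistic platform noise beyond the configured rules. Passing
tests therefore demonstrate that the *accounting* is exact and the
*statistics* behave as designed, not that real data will be as clean.

## Study conditions baked into defaults

Where a quantitative condition is exercised, the generator uses the
documented study conditions rather than tunable knobs: the multi-sample
outlier exercise uses 30 profiles with 9 outliers at pair-deviation
Δ = 1.5 percentage points and within-group deviation sd σ = 0.2 (σ is
defined on the pair deviation — the quantity the clustering consumes — so
per-category noise is σ/√2); the four-cycle pattern fixture plants A>G at
cycles {20, 52, 65, 136} in R2F with G_G context; the discordant-pair
fixture plants long-insert pairs at 1.2% of mapped reads; the case-study
fixture targets a 1.87% mean per-cycle rate with an end-loaded
(phasing-style) rise — multiplier 0.85 + 1.65·(c/L)¹⁰, mean 1 — matched
quality decay, and a single spiked cycle at ~2.4%. The end-loaded shape is
a deliberate choice: phasing error concentrates at read ends with a
comparatively flat mid-read profile, which is also the regime in which a
2.4%-vs-1.87% spike is a significant Dixon outlier against its window.

# Numerical and degenerate-input choices

* Counts are integers throughout; rates are derived, never accumulated, so
  truth comparisons demand exact count equality and 1e-9 on rates.
* Percentage tables are defined only where their denominator is positive;
  otherwise NA (e.g. category percentages of a mismatch-free sample).
* The per-cycle/quality correlation needs ≥3 cycles with mismatches and
  nonzero variance on both sides; otherwise NA.
* Ward/Euclidean clustering is deterministic given the matrix; ties break
  by sample order (the order rows are supplied).
* An empty BAM yields a zero-count result with a warning, headers-only
  logs, and placeholder report panels.
* Mixed read lengths size per-cycle arrays to the maximum; denominators
  reflect actual per-cycle coverage.
* BED input is 0-based half-open; everything user-facing is 1-based
  closed. Site queries accept `chr1:100` and `chr1:100-100`.

# Problem sizes

The shipped test-suite fixtures use 500–1 500 pairs for module tests and a
50 000-pair, 148 bp fixture for the end-to-end accounting check; the
acceptance script uses 20 000-pair fixtures, 100 clustering replicates,
1 000 Dixon vectors and n = 20 000/10 000 for the logistic checks. These
sizes give exact-count assertions and stochastic checks with comfortable
margins while keeping a full run in the low minutes on one CPU; the
accumulator itself streams in bounded memory and scales linearly, so the
same code handles full-depth genomes.

# Known limitations

Single-end data are rejected rather than approximated. Overlapping mates
are counted twice in depth and profiles (logged as a caveat, consistent
with a base-level definition of depth). CRAM is readable only insofar as
the underlying htslib layer converts it; CRAM writing is out of scope, as
are recalibration, realignment, variant calling and CNV inference. Dixon's
test assumes approximate normality of the window values and flags at most
one outlier per call; the two-pass window exclusion mitigates, but does not
eliminate, masking with ≥3 coincident spikes inside one window.
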