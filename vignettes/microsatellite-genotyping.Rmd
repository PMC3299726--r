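---
title: "Gap-invariant microsatellite genotyping: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-invariant microsatellite genotyping: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsat)
library(dplyr)
```

## The problem and the model

Microsatellites — tandem repetitions of a 1–5 base unit — mutate by gaining
and losing repeat units orders of magnitude faster than point mutations
accumulate, which makes them informative markers and candidate drivers of
quantitative variation, but also makes them the worst case for standard
variant callers. Inside a repeat tract there is no way to say *which* copy
of the unit an indel hit: an aligner may place the same 2-base deletion at
the start, middle or end of the tract, and a SNP/indel caller will then
report several spurious alleles for one molecule of history.

`microsat` sidesteps the homology problem by scoring genotypes as **allele
lengths**. For a locus occupying the reference interval `[s, e)` (0-based,
half-open), the two anchors are the last non-repetitive base before the
tract (`s − 1`) and the first after it (`e`). If both anchors are aligned,
the read's allele is

    allele = qoff(e) − qoff(s − 1) − 1

in read coordinates. Every tract-internal gap placement of the same edit
yields the same value (this is asserted exhaustively in the test suite over
randomized CIGAR re-placements), so reads of one allele can never disagree
because of alignment ambiguity.

The accuracy model leans on a biological assumption: the lines being
genotyped are inbred to (near-)homozygosity, so all reads of a line at a
locus carry one true allele, and the spread of read-level calls measures
error, not heterozygosity. That gives two metrics:

* **completeness** — the fraction of catalog loci with at least two
  scorable reads (a genotype can be assigned);
* **internal concordance** — `R_major / R_total`, the fraction of a locus's
  scorable reads supporting the majority allele.

Residual heterozygosity breaks the assumption locally, so chromosome arms
whose SNP genotypes are more than 5% heterozygous in a line (strictly
greater) are excluded from that line's cells before either metric is
computed.

## Read scorability and its parameters

A read contributes to a genotype only if it

1. **spans** the tract with both anchor bases aligned (a deleted anchor is
   `unanchored`; a read ending inside the tract is `not_spanning`);
2. matches the reference at `min_flank` consecutive positions outward from
   each boundary (default **3**): mismatched or degraded flanks are the
   visible signature of mismapped reads and of alignment slippage, and
   the flank run is terminated by a mismatch, an alignment gap, or the end
   of the read. A mismatched anchor base counts as a flank mismatch, not a
   missing anchor; insertions immediately inside the anchors belong to the
   allele, insertions outside them break the flank run;
3. is **uniquely mapped** (default MapQ > 0 and no alternative-hit tag) —
   repeats attract reads from paralogous loci, and those reads carry the
   wrong allele.

`min_flank = 3` is the default because the completeness cost of each
further flank base soon outruns its concordance benefit; the package's
flank-sweep utilities (and the acceptance script) recompute that trade-off
on synthetic data, where scorable-read counts and completeness are exactly
non-increasing in `min_flank` while mean concordance is non-decreasing.
`min_flank = 1` reproduces the most permissive sensible setting. A genotype
requires `min_reads = 2` scorable reads; an exact tie for the modal allele
yields `ambiguous_tie` and no genotype, because a tie in a homozygous line
signals error — we deliberately do not break ties toward the shorter
allele, which would hard-code a length bias.

Base qualities are read but not used for filtering; in this design the
flank-match criterion subsumes them, since a low-quality flank fails to
match the reference.

## The catalog

The detector compares each base to the base *u* positions earlier
(*u* = 1..5), scores matches +2 and mismatches −5, and reports
maximal-scoring runs (Ruzzo–Tompa all-maximal-subsequences, implemented in
C++) whose score, with the seed unit credited as matched, reaches 14 — so a
perfect 7-base tract is the shortest reportable locus at every unit size.
The native detector allows no indels inside the tract; this keeps it
exactly checkable against an exhaustive brute-force scorer, which the test
suite does on randomly planted repeats. TRF `.dat` output can be ingested
instead when indel-containing tracts matter.

Numerical conventions fixed here (the field's file formats disagree, so
they are explicit):

* coordinates are 0-based half-open internally; TRF and RepeatMasker rows
  (1-based inclusive) are converted on ingest, BED is taken as-is;
* the reported unit is the lexicographically minimal rotation of the modal
  u-mer; reverse-complement units are *not* merged (calls are made on the
  reference strand);
* purity = matching offset-*u* comparisons / (tract length − *u*); the
  analysis floor is purity ≥ 0.80, inclusive;
* deduplication: overlapping same-unit hits, or nested hits of any unit,
  keep the higher score; ties prefer the longer, then leftmost, then
  smaller-unit hit. The last tie-break matters because a perfect tract of
  unit *u* scores identically at unit 2*u* over the identical interval;
* repetitive-element proximity: a locus within 20 bases (edge to edge,
  inclusive) of an annotation interval is flagged; "Simple_repeat" and
  "Low_complexity" annotations are dropped first, since they are the
  microsatellites themselves;
* heterochromatic sequences (default: names ending "Het", plus "U") are
  flagged rather than deleted, and every flag excludes a locus from all
  downstream analyses.

## Population statistics

Per locus, the allele spectrum across lines records the modal allele (ties
to the smaller allele), the number of distinct alleles, and the deltas of
non-modal alleles *measured against the population's modal allele*, not the
reference — the modal allele is the best available stand-in for the
ancestral state. Loci called in fewer than two lines are skipped.
Variability summaries (mean distinct alleles by modal-length bin, within
unit-size or purity classes) suppress bins under 25 loci and exclude
mononucleotides, whose apparent variation is dominated by sequencing
slippage. The in-phase analysis reports, per unit size and length bin, the
percentage of deltas that are exact unit multiples; by default it uses only
uninterrupted (purity 1) tracts. Unit-delta histograms divide deltas by the
unit length (2-base events in tetranucleotides land at half-integers) after
filtering to ≥ 90% purity and unit-specific minimum lengths
(13/20/23/27 bases for units 2–5).

"Approaches a plateau" is made operational in `plateau_length()`: the
asymptote is the mean percent-in-phase over the top length quartile, and
the plateau is the smallest length bin reaching 95% of it (bins with fewer
than 5 variant alleles are ignored). The criterion is deliberately scale
free, so it recovers a programmed slippage-onset length without knowing the
asymptote's level.

The read-length bias bootstrap resamples discordant loci with replacement
(default 1,000 trials), tabulates per-bin frequencies of
`call − reference length` per read-length group, and reports the 2.5th and
97.5th percentiles across trials per bin; the seed is stored in the result
object so bands are reproducible. Under a null where both groups share one
delta distribution, the bands' empirical coverage sits near 95% (the
acceptance script measures it at 300 loci × 200 repetitions).

Smoothing everywhere is the unweighted mean over a ±2 window of whatever
bins exist, with truncated windows at the ends. Binned accuracy metrics
average per-line bin means over lines by default (`pooled = TRUE` switches
to pooling cells), since the per-line average is robust to one badly
sequenced line dominating a bin.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; its defaults are chosen once to
mirror a realistic inbred-panel resequencing design and are not tuned per
analysis:

* **reference**: 3 chromosomes, 200 planted loci spread over unit sizes
  1–5, tract lengths 7 + Geometric(0.134) capped at 40 — right-skewed with
  median near 11 and ~90% below 23 bases, matching the length profile of
  compact insect genomes; ~15% of tracts ≥ 15 bases carry internal
  interruptions (purity ~0.85–0.97). Planted loci are separated by at
  least twice the read length of unique flank, and three guard bases per
  side (the most that can simultaneously mismatch all unit offsets 1–5
  over a 4-letter alphabet), plus a redraw check, guarantee each perfect
  planted tract is the maximal repeat at its position — otherwise chance
  flank matches would make "exact coordinate recovery" unattainable by any
  detector;
* **panel**: 20 lines; per locus and line the allele is the reference
  length plus a sum of signed steps, Poisson in number with intensity
  `0.3 × length × purity / (10 × unit size)` — increasing in tract length
  and purity, decreasing in unit size, the canonical ordering of repeat
  instability. Steps are whole units with probability
  `whole_unit_fraction` (default 1.0, the pure stepwise model); the
  remainder are 1–2 base events that are never unit multiples. Whole-unit
  slippage can be switched off below per-unit threshold lengths to create
  a programmed mutability onset;
* **reads**: single-end 75-base reads at 20× mean depth, drawn uniformly
  along each line's mutated chromosome and emitted pre-aligned, with the
  planted indel placed at a uniformly random position inside the tract so
  the gap-invariance property is exercised rather than assumed.
  Substitution errors are i.i.d. (optionally ramped toward the 3' end),
  slippage errors add or remove one unit during tract traversal
  (concentrated in homopolymers; rate × 0.1 for units ≥ 2), and a
  configurable fraction of spanning reads is relocated to a different
  same-unit locus with MapQ degraded — flank mismatches at the false locus
  then arise naturally.

Because reads are emitted pre-aligned, the generator simulates the *output*
of a mapping step, not the mapper: real aligner pathologies (soft-clipping
into tracts, local realignment differences, reference-biased gap opening)
are outside its vocabulary. Reads that only partially overlap a mutated
tract carry plain match CIGARs; they are unscorable at that locus under
the spanning rule, so accuracy metrics are unaffected, but this is another
respect in which the synthetic alignments are cleaner than BWA output.
Paired-end structure, insert-size distributions and realistic quality
strings are not modeled. Passing tests therefore demonstrate the
correctness of the scoring, calling and summary logic under a faithful
generative model of repeat variation — not robustness to every artifact of
a particular aligner.

One generative subtlety worth knowing when interpreting in-phase numbers:
with `whole_unit_fraction = p`, the *visible* in-phase share sits slightly
below *p*, because opposite-sign whole-unit step pairs cancel into an
invisible (delta 0) allele while mixed whole-unit/non-unit pairs never
cancel. The effect shrinks with mutation intensity; the package's own
checks therefore estimate *p* on a large panel at low intensity
(260 loci × 200 lines at intensity 0.12), where most variant alleles arise
from a single step.

## Problem sizes and numerical choices in the built-in checks

The shipped tests and `scripts/acceptance.R` run entirely on synthetic
data at sizes chosen to give tight statistics while staying desk-scale:
error-free recovery uses 3 chromosomes × 200 loci × 20 lines at 20×
(~200,000 reads, ~4,000 genotype cells); the flank sweep averages 20
replicates of a 20-locus, 3-line noisy fixture (1% substitutions, 2%
mismapped reads); plateau recovery plants 6 loci at each of 16 lengths
around each programmed onset for units 2–5 and evaluates the panel's
genotype table directly; the bootstrap calibration draws 200 panels of 300
discordant loci. All randomness in the acceptance script derives from its
`--seed` argument.

## Known limitations

* Diploid/heterozygous genotype calling is out of scope; the caller
  assumes one allele per line and treats ties as errors.
* The native detector has no tract-internal indel model; catalogs for
  indel-rich imperfect repeats should come through the TRF ingest path.
* Unique-mapping detection depends on aligner tags; without them it
  reduces to MapQ > 0.
* Allele lengths beyond `read length − 2 × min_flank` are structurally
  uncallable from a given read size; completeness near that boundary
  reflects the read length, not the method.
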