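# microsat

Genotype microsatellites (short tandem repeats, unit sizes 1–5) from
reference-mapped short reads, and summarise repeat variation across panels
of homozygous inbred lines.

Repeat loci are hard to call with SNP/indel machinery because there is no
sound basis for inferring homology between aligned copies of a repeated
unit: the same deletion can legitimately be placed anywhere inside the
tract, so naive calling fragments one allele into many. `microsat` instead
scores each read by **allele length** — the number of read bases between the
two non-repetitive flanking anchors of the locus — which is invariant to
where the aligner placed gaps inside the tract. The package is aimed at
population and quantitative geneticists working with inbred/isogenic panels
(fly, worm, plant RIL collections) where per-line homozygosity makes read
agreement a direct accuracy measure.

## The method

For a catalog locus with reference tract `[s, e)` on a chromosome, a read is
**scorable** when

1. it spans the entire tract, with both anchor bases (`s−1` and `e`, 0-based)
   aligned;
2. at least *k* consecutive flanking positions adjacent to each repeat
   boundary match the reference (default *k* = 3; a mismatch, gap, or read
   end terminates the run);
3. it is uniquely mapped (MapQ > 0 and no alternative-hit annotation).

The read's allele is `qoff(e) − qoff(s−1) − 1` in read coordinates —
insertions between the anchors lengthen it, deletions shorten it, and two
placements of the same gap give identical calls. A genotype needs at least
two scorable reads; the call is the modal allele length and its **internal
concordance** is

```
C = R_major / R_total
```

the fraction of scorable reads supporting the majority allele (meaningful
because inbred lines are homozygous; exact ties yield no call).
**Completeness** is the fraction of loci with at least two scorable reads.

The catalog side reproduces a TRF-style identification pipeline: a native
detector scores offset-*u* self-comparisons (match +2, mismatch −5, minimum
score 14, so 7 bases is the shortest reportable tract), with redundant-hit
deduplication, RepeatMasker-proximity (≤ 20 bases), heterochromatin, and
purity (≥ 0.80) filters. Population summaries cover allele spectra, distinct
allele counts against tract length/purity/unit size, the percent of
variation **in phase** (whole-unit multiples of the repeat, the stepwise
mutation model's signature), unit-delta histograms, and a bootstrap test for
read-length bias at discordantly genotyped loci.

Everything is testable without external data: a generator plants repeats
with known coordinates into synthetic chromosomes, evolves line panels by
(mostly) whole-unit stepwise mutation, and emits pre-aligned reads with
substitution, slippage and mismapping errors plus a per-read truth table.

## Worked example

```r
library(microsat)
library(dplyr)

cfg <- sim_config(seed = 42, n_loci = 60, n_lines = 5, coverage = 15,
                  intensity = 0.4, sub_error = 0.005)
ds  <- simulate_dataset(cfg)

calls <- genotype_panel(ds$catalog, ds$alignments, ds$reference$sequences,
                        min_flank = 3, min_reads = 2)
completeness(calls)
#> # A tibble: 1 × 2
#>   n_loci completeness
#>    <int>        <dbl>
#> 1    300            1

calls %>% filter(status == "called") %>%
  summarise(mean_concordance = mean(concordance))
#> # A tibble: 1 × 1
#>   mean_concordance
#>              <dbl>
#> 1                1

head(genotype_matrix(calls), 3)
#> # A tibble: 3 × 6
#>   locus_id       line01 line02 line03 line04 line05
#>   <chr>          <chr>  <chr>  <chr>  <chr>  <chr>
#> 1 chr1_1124_1132 8      8      8      8      8
#> 2 chr1_1312_1322 10     14     10     10     10
#> 3 chr1_1493_1502 9      9      7      9      9
```

All 300 locus × line cells are genotyped (completeness 1) and every
scorable read agrees with its line's call (mean concordance 1): the 0.5%
substitution error rate costs scorable reads at the flank filter but cannot
corrupt an allele length. The matrix rows show one monomorphic locus and
two loci with whole-unit variant lines (10→14 is two AC units, 9→7 one
dinucleotide unit). Downstream,

```r
spectra <- build_allele_spectra(calls)
in_phase_analysis(spectra, ds$catalog)   # % whole-unit variation by length
unit_delta_histogram(spectra, ds$catalog)
```

quantify how closely the panel follows stepwise mutation, and
`plot_metric_by_bin()`, `plot_in_phase()`, `autoplot()` (for
`bootstrap_bias_test()` results) draw the standard diagnostics.

A thin command-line wrapper (`inst/cli/microsat`) exposes `catalog`,
`genotype`, `simulate`, `run` and `selftest` subcommands over the same
functions. If you produce your own BAMs, any aligner works; the package
consumes coordinate-sorted SAM/BAM and only requires that alternative-hit
tags (e.g. BWA's `XT`/`X1`/`XA`) be present if you want the unique-mapping
criterion to be stricter than MapQ > 0.

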