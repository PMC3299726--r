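Package: microsat
Title: Microsatellite Genotyping and Population Analysis from
    Reference-Mapped Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and filters a catalog of short tandem repeats (unit
    sizes 1-5) from a reference genome, calls allele-length genotypes in
    homozygous inbred lines from reference-mapped reads using a
    gap-invariant length rule with spanning, flank-match and unique-mapping
    read filters, and assesses call quality through completeness, internal
    concordance, read-length stratified comparisons and a bootstrap bias
    test. Population-scale summaries cover allele spectra, variability
    correlates (tract length, purity, unit size), in-phase (whole-unit)
    stepwise-mutation statistics and unit-delta histograms. A fully
    synthetic, ground-truthed data generator (reference with planted
    repeats, stepwise-mutated line panels, pre-aligned reads with
    substitution, slippage and mismapping errors) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
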