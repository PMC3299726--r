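#' Exclude chromosome arms with residual heterozygosity
#'
#' The inbred-line concordance metric assumes homozygosity, so a chromosome
#' arm is excluded for a line when more than `threshold` of its SNP sites
#' were scored heterozygous (strictly greater: 5 het sites out of 100 at the
#' default threshold are retained, 6 are excluded).
#'
#' @param het_sites tibble with `line_id`, `chrom`, `n_het`, `n_total`.
#' @param threshold maximum tolerated heterozygous fraction.
#' @return tibble of excluded (`line_id`, `chrom`) pairs with `het_fraction`.
#' @export
exclude_heterozygous_arms <- function(het_sites, threshold = 0.05) {
  het_sites %>%
    mutate(het_fraction = if_else(.data$n_total > 0,
                                  .data$n_het / .data$n_total, 0)) %>%
    filter(.data$het_fraction > threshold) %>%
    select(all_of(c("line_id", "chrom", "het_fraction")))
}

#' Completeness of genotype calls
#'
#' The proportion of loci for which a genotype could be assigned, i.e. with
#' at least `min_reads` scorable reads. Cells excluded for residual
#' heterozygosity are removed from the denominator.
#'
#' @param calls calls tibble.
#' @param min_reads minimum scorable reads defining a valid genotype.
#' @param by optional grouping columns (e.g. `"line_id"`).
#' @return tibble with `n_loci` and `completeness` (per group when `by` is
#'   given).
#' @export
completeness <- function(calls, min_reads = 2L, by = NULL) {
  x <- filter(calls, .data$status != "excluded_het")
  if (!is.null(by)) x <- group_by(x, across(all_of(by)))
  summarise(x, n_loci = n(),
            completeness = mean(.data$n_scorable >= min_reads),
            .groups = "drop")
}

#' Sliding-window smoothing over an integer-indexed series
#'
#' Unweighted mean over the values observed at indices within `window` of
#' each index; indices missing from the series are simply absent from the
#' window, so endpoints use the truncated window.
#'
#' @param x integer index (e.g. reference length).
#' @param y values.
#' @param window half-width in index units.
#' @return numeric vector of smoothed values aligned with `x`.
#' @export
smooth_series <- function(x, y, window = 2L) {
  vapply(x, function(xi) mean(y[abs(x - xi) <= window], na.rm = TRUE),
         double(1))
}

#' Bin completeness and concordance by a locus attribute
#'
#' Joins calls to catalog attributes and aggregates the two accuracy
#' metrics per bin, with a smoothed copy of each (window of +-2 bins by
#' default, applied only to numeric bin keys). By default per-line bin
#' means are computed first and then averaged over lines; `pooled = TRUE`
#' aggregates all cells directly.
#'
#' @param calls calls tibble.
#' @param catalog catalog tibble.
#' @param by locus attribute to bin on: "ref_length", "unit_length" or
#'   "purity".
#' @param window smoothing half-width (bins).
#' @param min_reads completeness threshold.
#' @param pooled pool cells across lines instead of averaging line means.
#' @return tibble with `bin`, `n_loci`, `completeness`, `concordance`,
#'   `completeness_smooth`, `concordance_smooth`.
#' @export
bin_metrics <- function(calls, catalog, by = "ref_length", window = 2L,
                        min_reads = 2L, pooled = FALSE) {
  x <- calls %>%
    filter(.data$status != "excluded_het") %>%
    left_join(select(catalog, all_of(c("locus_id", by))), by = "locus_id") %>%
    rename(bin = all_of(by))
  grp <- if (pooled || !"line_id" %in% names(x)) "bin" else c("line_id", "bin")
  agg <- x %>%
    group_by(across(all_of(grp))) %>%
    summarise(n_loci = n(),
              completeness = mean(.data$n_scorable >= min_reads),
              concordance = mean(.data$concordance[.data$status == "called"]),
              .groups = "drop")
  if (!identical(grp, "bin")) {
    agg <- agg %>%
      group_by(.data$bin) %>%
      summarise(n_loci = sum(.data$n_loci),
                completeness = mean(.data$completeness, na.rm = TRUE),
                concordance = mean(.data$concordance, na.rm = TRUE),
                .groups = "drop")
  }
  agg <- arrange(agg, .data$bin)
  if (is.numeric(agg$bin)) {
    agg$completeness_smooth <- smooth_series(agg$bin, agg$completeness, window)
    agg$concordance_smooth <- smooth_series(agg$bin, agg$concordance, window)
  } else {
    agg$completeness_smooth <- agg$completeness
    agg$concordance_smooth <- agg$concordance
  }
  agg
}

#' Compare genotypes called from two read-length groups
#'
#' Splits one line's reads by read length, calls genotypes independently in
#' each group, and reports loci that were called in both groups with
#' differing majority alleles. Loci called in only one group are excluded
#' from the comparison.
#'
#' @param alignments alignment tibble for one or more lines (with
#'   `line_id`).
#' @param catalog catalog tibble.
#' @param reference named character vector of chromosomes.
#' @param group_a,group_b predicate read lengths: a read belongs to group A
#'   when its length equals (or, for vectors, is contained in) `group_a`.
#' @param ... passed to [genotype_panel()].
#' @return list with `calls_a`, `calls_b` and `discordant` (locus, line,
#'   both alleles, reference length, and per-group deltas call - reference).
#' @export
compare_read_length_groups <- function(alignments, catalog, reference,
                                       group_a = 45L, group_b = 75L, ...) {
  if (!"line_id" %in% names(alignments)) alignments$line_id <- "line1"
  rl <- if ("read_length" %in% names(alignments)) {
    alignments$read_length
  } else nchar(alignments$seq)
  a <- alignments[rl %in% group_a, , drop = FALSE]
  b <- alignments[rl %in% group_b, , drop = FALSE]
  calls_a <- genotype_panel(catalog, a, reference, ...)
  calls_b <- genotype_panel(catalog, b, reference, ...)
  both <- inner_join(
    calls_a %>% filter(.data$status == "called") %>%
      select(all_of(c("locus_id", "line_id", "majority_allele"))) %>%
      rename(allele_a = "majority_allele"),
    calls_b %>% filter(.data$status == "called") %>%
      select(all_of(c("locus_id", "line_id", "majority_allele"))) %>%
      rename(allele_b = "majority_allele"),
    by = c("locus_id", "line_id"))
  disc <- both %>%
    filter(.data$allele_a != .data$allele_b) %>%
    left_join(select(catalog, all_of(c("locus_id", "ref_length"))),
              by = "locus_id") %>%
    mutate(delta_a = .data$allele_a - .data$ref_length,
           delta_b = .data$allele_b - .data$ref_length)
  list(calls_a = calls_a, calls_b = calls_b, discordant = disc,
       n_compared = nrow(both))
}

#' Bootstrap test for read-length allele bias
#'
#' At loci genotyped discordantly between two read-length groups, tabulates
#' the frequency distribution of allele-length difference from the
#' reference (call - reference length) per group, and attaches 95%
#' confidence bands obtained by resampling loci with replacement: in each
#' of `n_trials` trials the discordant loci are resampled (same n), the
#' per-bin frequencies recomputed, and the 2.5th and 97.5th percentiles
#' across trials reported per bin. A fixed `seed` makes the bands
#' reproducible.
#'
#' @param discordant discordant-locus tibble from
#'   [compare_read_length_groups()] (needs `delta_a`, `delta_b`).
#' @param n_trials number of bootstrap resamples.
#' @param seed RNG seed recorded in the result.
#' @param probs lower/upper band percentiles.
#' @return an object of class `msat_bias_test`; see [tidy.msat_bias_test()].
#' @export
bootstrap_bias_test <- function(discordant, n_trials = 1000L, seed = 1L,
                                probs = c(0.025, 0.975)) {
  n <- nrow(discordant)
  if (n == 0L) stop("no discordant records to resample", call. = FALSE)
  deltas <- list(a = discordant$delta_a, b = discordant$delta_b)
  bins <- sort(unique(c(deltas$a, deltas$b)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  idx <- matrix(sample.int(n, n * n_trials, replace = TRUE), nrow = n_trials)
  per_group <- lapply(deltas, function(d) {
    res <- matrix(d[idx], nrow = n_trials)
    obs <- vapply(bins, function(b) mean(d == b), double(1))
    lo <- hi <- double(length(bins))
    for (k in seq_along(bins)) {
      fr <- rowMeans(res == bins[k])
      q <- stats::quantile(fr, probs, names = FALSE, type = 7)
      lo[k] <- q[1]; hi[k] <- q[2]
    }
    tibble(delta = bins, freq = obs, lo = lo, hi = hi)
  })
  out <- list(
    bands = bind_rows(a = per_group$a, b = per_group$b, .id = "group"),
    n_discordant = n, n_trials = n_trials, seed = seed, probs = probs)
  class(out) <- "msat_bias_test"
  out
}

#' @export
print.msat_bias_test <- function(x, ...) {
  cat("Read-length bias bootstrap:", x$n_discordant, "discordant loci,",
      x$n_trials, "trials (seed", x$seed, ")\n")
  print(x$bands, n = 20)
  invisible(x)
}

#' MapQ diagnostics for called loci
#'
#' Two mapping-quality diagnostics: (a) the Pearson correlation, across
#' reference-length bins, between the bin mean of per-locus mean MapQ and
#' the bin mean concordance (NA when fewer than two bins are available);
#' (b) for loci whose scorable-read allele multiset is n:1 with n of at
#' least `min_majority`, the relative difference between the mean MapQ of
#' the discordant singleton reads and the mean MapQ of majority reads.
#'
#' @param scored scored-read tibble from [score_reads()] (with `line_id`
#'   when calls carry lines).
#' @param calls calls tibble.
#' @param catalog catalog tibble.
#' @param min_majority minimum majority count n for the n:1 comparison.
#' @return list with `length_bin_correlation`, `singleton_rel_diff`,
#'   `n_singleton_loci`.
#' @export
mapq_diagnostics <- function(scored, calls, catalog, min_majority = 4L) {
  keys <- intersect(c("locus_id", "line_id"), names(calls))
  sc <- filter(scored, .data$scorable)
  locus_mapq <- sc %>%
    group_by(across(all_of(keys))) %>%
    summarise(mean_mapq = mean(.data$mapq), .groups = "drop")
  per_bin <- calls %>%
    filter(.data$status == "called") %>%
    left_join(locus_mapq, by = keys) %>%
    left_join(select(catalog, all_of(c("locus_id", "ref_length"))),
              by = "locus_id") %>%
    group_by(.data$ref_length) %>%
    summarise(mean_mapq = mean(.data$mean_mapq, na.rm = TRUE),
              mean_concordance = mean(.data$concordance), .groups = "drop")
  r <- if (nrow(per_bin) >= 2L &&
           stats::sd(per_bin$mean_mapq) > 0 &&
           stats::sd(per_bin$mean_concordance) > 0) {
    stats::cor(per_bin$mean_mapq, per_bin$mean_concordance)
  } else NA_real_
  # n:1 loci: exactly two distinct alleles, counts (n >= min_majority, 1)
  n1 <- calls %>%
    filter(.data$status == "called") %>%
    mutate(n_alleles = vapply(.data$allele_counts, length, integer(1)),
           minority = vapply(.data$allele_counts, function(x) {
             if (length(x) < 2L) NA_integer_ else as.integer(sort(x)[1])
           }, integer(1))) %>%
    filter(.data$n_alleles == 2L, .data$minority == 1L,
           .data$n_scorable - 1L >= min_majority)
  if (nrow(n1) == 0L) {
    return(list(length_bin_correlation = r,
                singleton_rel_diff = NA_real_, n_singleton_loci = 0L))
  }
  sc2 <- sc %>%
    inner_join(select(n1, all_of(c(keys, "majority_allele"))), by = keys) %>%
    mutate(is_major = .data$allele_length == .data$majority_allele)
  mq_major <- mean(sc2$mapq[sc2$is_major])
  mq_single <- mean(sc2$mapq[!sc2$is_major])
  list(length_bin_correlation = r,
       singleton_rel_diff = (mq_single - mq_major) / mq_major,
       n_singleton_loci = nrow(n1))
}
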