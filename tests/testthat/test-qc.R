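test_that("heterozygous arm exclusion uses a strict 5% threshold", {
  het <- tibble::tibble(
    line_id = c("l1", "l2", "l3"), chrom = "2L",
    n_het = c(6L, 5L, 0L), n_total = c(100L, 100L, 80L))
  ex <- exclude_heterozygous_arms(het)
  expect_equal(ex$line_id, "l1") # 6% out, 5% and 0% retained
})

test_that("completeness is the fraction of loci with enough reads", {
  calls <- tibble::tibble(
    locus_id = paste0("L", 1:4), line_id = "l1",
    n_scorable = c(3L, 2L, 5L, 1L),
    status = c("called", "called", "ambiguous_tie", "insufficient_reads"))
  expect_equal(completeness(calls)$completeness, 0.75)
  calls$n_scorable <- 0L
  expect_equal(completeness(calls)$completeness, 0)
  # excluded cells leave the denominator
  calls2 <- tibble::tibble(locus_id = paste0("L", 1:4), line_id = "l1",
                           n_scorable = c(3L, 3L, 0L, 0L),
                           status = c("called", "called",
                                      "insufficient_reads", "excluded_het"))
  expect_equal(completeness(calls2)$completeness, 2 / 3)
})

test_that("window smoothing averages whatever the window contains", {
  expect_equal(smooth_series(1:10, rep(0.4, 10)), rep(0.4, 10))
  x <- 10:14
  y <- c(0, 0, 1, 0, 0)
  expect_equal(smooth_series(x, y)[3], 0.2)
  expect_equal(smooth_series(5L, 0.7), 0.7)
  # truncated endpoint: mean of the three values in reach
  expect_equal(smooth_series(x, y)[1], mean(y[1:3]))
})

test_that("read-length group comparison reports only double-called conflicts", {
  toy <- toy_locus()
  short_read <- function(name, cigar = "40M", pos = 22L) {
    r <- make_read(toy$ref, pos, cigar, name = name, line_id = "l1")
    r$read_length <- 45L
    r
  }
  long_read <- function(name, pos = 18L) {
    r <- make_read(toy$ref, pos, "50M", name = name, line_id = "l1")
    r$read_length <- 75L
    r
  }
  # identical alleles in both groups: nothing discordant
  al <- dplyr::bind_rows(short_read("s1"), short_read("s2"),
                         long_read("g1"), long_read("g2"))
  cmp <- compare_read_length_groups(al, toy$catalog, toy$ref,
                                    group_a = 45L, group_b = 75L)
  expect_equal(nrow(cmp$discordant), 0L)
  expect_equal(cmp$n_compared, 1L)

  # short reads carry a 2-base deletion: group calls disagree
  al2 <- dplyr::bind_rows(short_read("s1", "12M2D30M"),
                          short_read("s2", "14M2D30M"),
                          long_read("g1"), long_read("g2"))
  cmp2 <- compare_read_length_groups(al2, toy$catalog, toy$ref,
                                     group_a = 45L, group_b = 75L)
  expect_equal(nrow(cmp2$discordant), 1L)
  expect_equal(cmp2$discordant$allele_a, 12L)
  expect_equal(cmp2$discordant$allele_b, 14L)
  expect_equal(cmp2$discordant$delta_a, -2L)
  expect_equal(cmp2$discordant$delta_b, 0L)

  # called in one group only: excluded from the comparison
  al3 <- dplyr::bind_rows(short_read("s1"), long_read("g1"), long_read("g2"))
  cmp3 <- compare_read_length_groups(al3, toy$catalog, toy$ref,
                                     group_a = 45L, group_b = 75L)
  expect_equal(cmp3$n_compared, 0L)
  expect_equal(nrow(cmp3$discordant), 0L)
})

test_that("the bias bootstrap is deterministic and degenerate when it must be", {
  disc <- tibble::tibble(delta_a = rep(-2L, 8), delta_b = rep(-2L, 8))
  bt <- bootstrap_bias_test(disc, n_trials = 200L, seed = 9L)
  expect_equal(bt$bands$freq, c(1, 1))
  expect_equal(bt$bands$lo, c(1, 1))
  expect_equal(bt$bands$hi, c(1, 1))

  disc2 <- tibble::tibble(delta_a = c(-2L, -1L, 0L, -2L, 1L, 0L, -1L, -2L),
                          delta_b = c(0L, 0L, 1L, -1L, 0L, 1L, 0L, -2L))
  b1 <- bootstrap_bias_test(disc2, n_trials = 300L, seed = 17L)
  b2 <- bootstrap_bias_test(disc2, n_trials = 300L, seed = 17L)
  expect_identical(b1$bands, b2$bands)
  expect_true(all(b1$bands$lo <= b1$bands$freq + 1e-12))
  expect_true(all(b1$bands$hi >= b1$bands$freq - 1e-12))
  # per-group observed frequencies sum to one
  sums <- tidy(b1) %>% dplyr::group_by(group) %>%
    dplyr::summarise(s = sum(freq))
  expect_equal(sums$s, c(1, 1))

  expect_error(bootstrap_bias_test(disc[0, ]), "no discordant")

  g <- glance(b1)
  expect_equal(g$n_discordant, 8L)
  expect_equal(g$mean_delta_a, mean(disc2$delta_a))
})

test_that("MapQ diagnostics quantify singleton reads and bin correlation", {
  mk_scored <- function(mapqs, alleles, locus = "L1") tibble::tibble(
    locus_id = locus, line_id = "l1",
    read_name = paste0(locus, "_r", seq_along(mapqs)),
    allele_length = alleles, flank_match_left = 5L, flank_match_right = 5L,
    mapq = mapqs, read_length = 75L, scorable = TRUE,
    rejection_reason = NA_character_)
  catalog <- tibble::tibble(locus_id = c("L1", "L2"),
                            ref_length = c(14L, 20L))
  # 4:1 multiset, all reads the same MapQ: relative difference 0
  sc <- mk_scored(rep(40L, 5), c(14L, 14L, 14L, 14L, 12L))
  calls <- call_loci(sc)
  d <- mapq_diagnostics(sc, calls, catalog)
  expect_equal(d$singleton_rel_diff, 0)
  expect_equal(d$n_singleton_loci, 1L)
  expect_true(is.na(d$length_bin_correlation)) # single length bin

  # singleton MapQ 10% below the majority reads
  sc2 <- mk_scored(c(40L, 40L, 40L, 40L, 36L), c(14L, 14L, 14L, 14L, 12L))
  d2 <- mapq_diagnostics(sc2, call_loci(sc2), catalog)
  expect_equal(d2$singleton_rel_diff, -0.10)
})

test_that("mean concordance degrades as injected error rises", {
  rates <- c(0, 0.01, 0.04)
  mean_conc <- vapply(rates, function(e) {
    cfg <- sim_config(seed = 61, n_loci = 30, n_lines = 3, coverage = 14,
                      sub_error = e, intensity = 0.3, slip_rate = e)
    ds <- simulate_dataset(cfg)
    calls <- genotype_panel(ds$catalog, ds$alignments,
                            ds$reference$sequences, min_flank = 1L)
    mean(calls$concordance[calls$status == "called"])
  }, double(1))
  expect_true(all(diff(mean_conc) <= 1e-9))
  expect_lt(mean_conc[3], 1)
})

test_that("homopolymers call less concordantly than pentanucleotides", {
  cfg <- sim_config(seed = 62, n_loci = 60, n_lines = 4, coverage = 15,
                    slip_rate = 0.12, intensity = 0.2)
  ds <- simulate_dataset(cfg)
  calls <- genotype_panel(ds$catalog, ds$alignments, ds$reference$sequences)
  by_unit <- calls %>%
    dplyr::filter(status == "called") %>%
    dplyr::left_join(dplyr::select(ds$catalog, locus_id, unit_length),
                     by = "locus_id") %>%
    dplyr::group_by(unit_length) %>%
    dplyr::summarise(conc = mean(concordance))
  expect_lt(by_unit$conc[by_unit$unit_length == 1L],
            by_unit$conc[by_unit$unit_length == 5L])
})

test_that("binned metrics carry raw and smoothed series of equal length", {
  cfg <- sim_config(seed = 63, n_loci = 40, n_lines = 3, coverage = 12,
                    sub_error = 0.01)
  ds <- simulate_dataset(cfg)
  calls <- genotype_panel(ds$catalog, ds$alignments, ds$reference$sequences)
  bins <- bin_metrics(calls, ds$catalog, by = "ref_length")
  expect_true(all(bins$completeness >= 0 & bins$completeness <= 1))
  expect_true(all(is.na(bins$concordance) |
                    (bins$concordance >= 0 & bins$concordance <= 1)))
  expect_equal(length(bins$completeness_smooth), nrow(bins))
  by_unit <- bin_metrics(calls, ds$catalog, by = "unit_length")
  expect_lte(nrow(by_unit), 5L)
})
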