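test_that("TRF dat parsing converts coordinates and filters by period", {
  dat <- c(
    "Tandem Repeats Finder Program",
    "Sequence: chr1 some description",
    "Parameters: 2 5 5 80 10 14 5",
    "10 23 2 7.0 2 95 0 24 50 50 0 0 1.92 AC ACACACACACACAC",
    "40 60 6 3.5 6 90 0 30 25 25 25 25 2.0 ACGTAC ACGTACACGTAC")
  loci <- parse_trf_dat(dat)
  expect_equal(nrow(loci), 1L) # the period-6 record is dropped
  expect_equal(loci$chrom, "chr1")
  expect_equal(loci$start, 9L) # 1-based inclusive 10 -> 0-based 9
  expect_equal(loci$end, 23L)
  expect_equal(loci$unit_length, 2L)
  expect_equal(loci$unit, "AC")
  expect_equal(loci$purity, 0.95)
  expect_equal(loci$ref_length, 14L)

  expect_equal(nrow(parse_trf_dat(character(0))), 0L)
  expect_error(parse_trf_dat(c("Sequence: chr1", "10 23 2")),
               "line 2")
  expect_error(parse_trf_dat("10 23 2 7.0 2 95 0 24 50 50 0 0 0 1.9 AC AC"),
               "Sequence")
  expect_error(
    parse_trf_dat(c("Sequence: chrX", dat[4]), chrom_names = c(chr1 = "2L")),
    "unknown sequence header")
})

test_that("native detector finds planted perfect repeats exactly", {
  set.seed(11)
  x <- plant_repeat("AC", 14L)
  loci <- find_tandem_repeats(x$seq, "chr1")
  hit <- loci[loci$start == x$start & loci$end == x$end, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "AC")
  expect_equal(hit$ref_length, 14L)
  expect_equal(hit$purity, 1)

  # a 7-base perfect mononucleotide is the shortest reportable tract
  y <- plant_repeat("A", 7L)
  ly <- find_tandem_repeats(y$seq, "c")
  expect_true(any(ly$start == y$start & ly$end == y$end & ly$unit == "A"))
  z <- paste0("CGTCGT", strrep("A", 6L), "CGTCGT")
  expect_false(any(find_tandem_repeats(z, "c")$unit == "A"))
})

test_that("detector purity matches direct mismatch counting", {
  set.seed(12)
  for (rep in 1:20) {
    u <- sample(1:5, 1)
    len <- sample(14:40, 1)
    x <- plant_repeat(random_unit_helper(u), len)
    s <- x$seq
    # knock one base in the middle of the tract
    p <- x$start + len %/% 2L
    old <- substr(s, p + 1L, p + 1L)
    substr(s, p + 1L, p + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
    loci <- find_tandem_repeats(s, "c")
    hit <- loci[loci$unit_length == u &
                  loci$start >= x$start - 1L & loci$end <= x$end + 1L, ]
    if (nrow(hit) == 1L) {
      m <- oracle_matches(s, hit$start, hit$end, u)
      expect_equal(hit$purity, m / (hit$ref_length - u))
      expect_lt(hit$purity, 1)
    }
  }
})

test_that("every detector hit is a genuine scoring interval and maximal", {
  set.seed(13)
  for (rep in 1:15) {
    s <- random_seq(200L)
    x <- plant_repeat(sample(c("A", "AC", "AAG", "AGAT", "AACGT"), 1),
                      sample(10:25, 1), flank = 40L)
    s <- paste0(s, x$seq)
    raw <- microsat:::rt_scan_cpp(s) # pre-dedup hits
    for (u in 1:5) {
      ora <- oracle_intervals(s, u)
      hits_u <- raw[raw$unit_length == u, ]
      if (nrow(hits_u)) {
        for (i in seq_len(nrow(hits_u))) {
          # reported score agrees with the exhaustive scorer
          expect_true(any(ora$start == hits_u$start[i] &
                            ora$end == hits_u$end[i] &
                            ora$score == hits_u$score[i]))
        }
      }
      # every exhaustively-scoring interval overlaps a reported hit
      if (nrow(ora)) {
        covered <- vapply(seq_len(nrow(ora)), function(k) {
          any(pmax(hits_u$start, ora$start[k]) <
                pmin(hits_u$end, ora$end[k]))
        }, logical(1))
        expect_true(all(covered))
      }
    }
  }
})

test_that("hit deduplication keeps the best of redundant hits", {
  base <- tibble::tibble(
    chrom = "c", start = 10L, end = 30L, unit = "AC", unit_length = 2L,
    purity = 1, ref_length = 20L, score = 40L)
  two <- dplyr::bind_rows(base, base)
  expect_equal(nrow(deduplicate_hits(two)), 1L)

  nested <- dplyr::bind_rows(
    base, # outer, score 40
    dplyr::mutate(base, start = 14L, end = 24L, ref_length = 10L,
                  unit = "GT", score = 20L)) # inner, different unit
  expect_equal(deduplicate_hits(nested)$score, 40L)

  disjoint <- dplyr::bind_rows(
    base, dplyr::mutate(base, start = 50L, end = 70L))
  expect_equal(nrow(deduplicate_hits(disjoint)), 2L)

  # same-unit overlap without containment: higher score wins
  shifted <- dplyr::bind_rows(
    base, dplyr::mutate(base, start = 20L, end = 40L, score = 30L))
  expect_equal(deduplicate_hits(shifted)$start, 10L)
})

test_that("RepeatMasker parsing filters classes and converts coordinates", {
  out <- c(
    "   SW   perc perc perc  query     position in query",
    "score   div. del. ins.  sequence  begin  end",
    "",
    "  463   1.3  0.6  1.7  2L        100    200 (22000) +  DNAREP1 LTR/Gypsy      1  100    (0)   1",
    "  239  11.4 21.5  1.3  2L        500    550 (21000) +  (TA)n    Simple_repeat  1   50    (0)   2",
    "  101   5.0  0.0  0.0  2L        700    750 (20000) +  A-rich   Low_complexity 1   50    (0)   3")
  res <- parse_repeatmasker_out(out)
  expect_equal(nrow(res), 1L)
  expect_equal(res$repeat_class, "LTR/Gypsy")
  expect_equal(res$start, 99L) # 1-based 100 -> 0-based 99
  expect_equal(res$end, 200L)
  expect_equal(nrow(parse_repeatmasker_out(out[1:3])), 0L)
  expect_error(parse_repeatmasker_out("463 1.3 0.6"), "malformed")
})

test_that("BED annotations keep 0-based coordinates and drop simple repeats", {
  bed <- c("2L\t99\t200\tLTR/Gypsy", "2L\t300\t350\tSimple_repeat")
  res <- read_annotation_bed(bed)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 99L)
})

test_that("repetitive-element proximity uses a 20-base edge gap", {
  mk <- function(start, end) tibble::tibble(
    locus_id = "x", chrom = "c", start = start, end = end, unit = "AC",
    unit_length = 2L, purity = 1, ref_length = end - start, score = 20L,
    re_proximal = FALSE, heterochromatic = FALSE, low_purity = FALSE)
  re <- function(start, end) tibble::tibble(chrom = "c", start = start,
                                            end = end, repeat_class = "LTR")
  expect_false(filter_near_repetitive_elements(
    mk(100L, 120L), re(141L, 200L))$re_proximal) # gap 21
  expect_true(filter_near_repetitive_elements(
    mk(100L, 120L), re(140L, 200L))$re_proximal) # gap 20
  expect_true(filter_near_repetitive_elements(
    mk(100L, 120L), re(110L, 200L))$re_proximal) # overlap
})

test_that("heterochromatin and purity flags follow their thresholds", {
  loci <- tibble::tibble(
    locus_id = c("a", "b", "c"), chrom = c("2RHet", "2L", "U"),
    start = 0L, end = 20L, unit = "AC", unit_length = 2L,
    purity = c(0.80, 0.79, 1.0), ref_length = 20L, score = 20L,
    re_proximal = FALSE, heterochromatic = FALSE, low_purity = FALSE)
  het <- exclude_heterochromatin(loci)
  expect_equal(het$heterochromatic, c(TRUE, FALSE, TRUE))
  expect_equal(exclude_heterochromatin(loci, character(0))$heterochromatic,
               rep(FALSE, 3))
  pur <- apply_purity_floor(loci)
  expect_equal(pur$low_purity, c(FALSE, TRUE, FALSE))
})

test_that("filter composition is order independent", {
  set.seed(31)
  loci <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:40),
    chrom = sample(c("2L", "2RHet", "U", "3R"), 40, TRUE),
    start = sample.int(5000, 40), unit = "AC", unit_length = 2L,
    purity = runif(40, 0.6, 1), score = 20L,
    re_proximal = FALSE, heterochromatic = FALSE, low_purity = FALSE)
  loci$end <- loci$start + sample(7:40, 40, TRUE)
  loci$ref_length <- loci$end - loci$start
  res <- tibble::tibble(chrom = sample(c("2L", "3R"), 15, TRUE),
                        start = sample.int(5000, 15),
                        repeat_class = "LTR")
  res$end <- res$start + 100L
  fns <- list(
    function(x) filter_near_repetitive_elements(x, res),
    function(x) exclude_heterochromatin(x),
    function(x) apply_purity_floor(x))
  flags <- function(x) x[order(x$locus_id),
                         c("re_proximal", "heterochromatic", "low_purity")]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  results <- lapply(perms, function(p) {
    flags(fns[[p[3]]](fns[[p[2]]](fns[[p[1]]](loci))))
  })
  for (k in 2:6) expect_identical(results[[k]], results[[1]])
})

test_that("catalog TSV round-trips and per-chromosome totals sum", {
  set.seed(32)
  cfg <- sim_config(seed = 32, n_loci = 30, n_chromosomes = 3)
  ref <- simulate_reference(cfg)
  loci <- apply_purity_floor(exclude_heterochromatin(ref$loci))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(loci, path)
  back <- read_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(loci))
  per_chrom <- table(loci$chrom)
  expect_equal(sum(per_chrom), nrow(loci))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_catalog_bed(loci, bed)
  expect_equal(length(readLines(bed)), nrow(loci))
})
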