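# toy locus geometry: tract occupies 0-based [30, 44); 1-based anchors are
# reference positions 30 (left) and 45 (right)

test_that("spanning, anchors and flank runs follow the scorability rules", {
  toy <- toy_locus()
  # gapless spanning read with perfect flanks
  sc <- score_toy(make_read(toy$ref, 20L, "35M"))
  expect_true(sc$scorable)
  expect_equal(sc$allele_length, 14L)
  expect_equal(sc$flank_match_left, 11L) # truncated by the read start
  expect_equal(sc$flank_match_right, 10L)

  # read ending on the last tract base: right flank absent
  sc <- score_toy(make_read(toy$ref, 20L, "25M"))
  expect_false(sc$scorable)
  expect_equal(sc$rejection_reason, "not_spanning")

  # deletion swallowing the right anchor base
  sc <- score_toy(make_read(toy$ref, 25L, "20M2D15M"))
  expect_equal(sc$rejection_reason, "unanchored")

  # substitution at the left anchor: flank run 0, still anchored
  r <- make_read(toy$ref, 20L, "35M")
  anchor_q <- 30L - 20L + 1L
  old <- substr(r$seq, anchor_q, anchor_q)
  substr(r$seq, anchor_q, anchor_q) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sc <- score_toy(r)
  expect_equal(sc$flank_match_left, 0L)
  expect_equal(sc$rejection_reason, "flank_mismatch")
  expect_equal(sc$allele_length, 14L) # anchored mismatch still yields length

  # insertion between the 2nd and 3rd flank position outside the boundary
  sc <- score_toy(make_read(toy$ref, 25L, "22M2I10M"))
  expect_equal(sc$flank_match_right, 2L)
})

test_that("allele length is gap-invariant and counts indels between anchors", {
  toy <- toy_locus()
  # the same 2-base deletion placed at every admissible tract position
  alleles <- vapply(0:12, function(g) {
    cig <- sprintf("%dM2D%dM", 6L + g, 30L - g)
    score_toy(make_read(toy$ref, 25L, cig))$allele_length
  }, integer(1))
  expect_true(all(alleles == 12L))

  # a 4-base insertion, several placements
  alleles <- vapply(1:13, function(g) {
    cig <- sprintf("%dM4I%dM", 5L + g, 31L - g)
    score_toy(make_read(toy$ref, 25L, cig))$allele_length
  }, integer(1))
  expect_true(all(alleles == 18L))
})

test_that("flank threshold and unique mapping gate scorability", {
  toy <- toy_locus()
  r <- make_read(toy$ref, 25L, "35M")
  expect_true(score_toy(r, min_flank = 3L)$scorable)
  expect_true(score_toy(r, min_flank = 5L)$scorable)
  # break the left flank two bases out from the anchor
  q <- 29L - 25L + 1L
  old <- substr(r$seq, q, q)
  substr(r$seq, q, q) <- setdiff(c("A", "C", "G", "T"), old)[1]
  sc <- score_toy(r, min_flank = 3L)
  expect_equal(sc$flank_match_left, 1L)
  expect_equal(sc$rejection_reason, "flank_mismatch")
  expect_true(score_toy(r, min_flank = 1L)$scorable)
  expect_true(score_toy(r, min_flank = 0L)$scorable)

  nu <- make_read(toy$ref, 25L, "35M", unique = FALSE)
  expect_equal(score_toy(nu)$rejection_reason, "not_unique")
  expect_true(score_toy(nu, require_unique = FALSE)$scorable)
})

test_that("a locus at the chromosome edge cannot be anchored", {
  toy <- toy_locus()
  cat0 <- dplyr::mutate(toy$catalog, locus_id = "c_0_14", start = 0L,
                        end = 14L)
  sc <- score_reads(make_read(toy$ref, 1L, "40M"), cat0, toy$ref)
  expect_false(sc$scorable)
  expect_equal(sc$rejection_reason, "unanchored")
})

test_that("raising min_flank never gains scorable reads", {
  set.seed(51)
  cfg <- sim_config(seed = 51, n_loci = 25, n_lines = 2, coverage = 12,
                    sub_error = 0.02, intensity = 0.3)
  ds <- simulate_dataset(cfg)
  n_scorable <- vapply(0:5, function(k) {
    sum(score_reads(ds$alignments, ds$catalog, ds$reference$sequences,
                    min_flank = k)$scorable)
  }, integer(1))
  expect_true(all(diff(n_scorable) <= 0L))
})

test_that("locus calling implements majority, concordance and ties", {
  mk <- function(alleles) tibble::tibble(
    locus_id = "L", read_name = paste0("r", seq_along(alleles)),
    allele_length = alleles, flank_match_left = 5L, flank_match_right = 5L,
    mapq = 37L, read_length = 75L, scorable = TRUE,
    rejection_reason = NA_character_)
  call <- call_loci(mk(c(14L, 14L, 14L, 14L, 12L)))
  expect_equal(call$status, "called")
  expect_equal(call$majority_allele, 14L)
  expect_equal(call$concordance, 0.8)
  expect_equal(call$n_scorable, 5L)

  expect_equal(call_loci(mk(14L))$status, "insufficient_reads")
  tie <- call_loci(mk(c(14L, 14L, 12L, 12L)))
  expect_equal(tie$status, "ambiguous_tie")
  expect_true(is.na(tie$majority_allele))
})

test_that("concordance is bounded and unanimity gives exactly 1", {
  set.seed(52)
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    alleles <- sample(c(12L, 14L, 16L), n, TRUE)
    call <- call_loci(tibble::tibble(
      locus_id = "L", read_name = paste0("r", 1:n), allele_length = alleles,
      flank_match_left = 5L, flank_match_right = 5L, mapq = 37L,
      read_length = 75L, scorable = TRUE, rejection_reason = NA_character_))
    if (call$status == "called") {
      expect_gt(call$concordance, 1 / n)
      expect_lte(call$concordance, 1)
      if (length(unique(alleles)) == 1L) expect_equal(call$concordance, 1)
    }
  }
})

test_that("genotype_panel fills all cells and honors arm exclusions", {
  toy <- toy_locus()
  reads <- function(line) dplyr::bind_rows(
    make_read(toy$ref, 20L, "35M", name = paste0(line, "_1")),
    make_read(toy$ref, 22L, "35M", name = paste0(line, "_2")))
  calls <- genotype_panel(toy$catalog,
                          list(l1 = reads("l1"), l2 = reads("l2")),
                          toy$ref)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$status == "called"))
  expect_true(all(calls$majority_allele == 14L))

  # no reads at all: the cell still exists with zero scorable reads
  calls0 <- genotype_panel(toy$catalog,
                           list(l1 = reads("l1"),
                                l2 = reads("l2")[0, ]), toy$ref)
  expect_equal(sum(calls0$n_scorable == 0L), 1L)

  ex <- tibble::tibble(line_id = "l2", chrom = "c")
  calls_ex <- genotype_panel(toy$catalog,
                             list(l1 = reads("l1"), l2 = reads("l2")),
                             toy$ref, excluded_arms = ex)
  expect_equal(calls_ex$status[calls_ex$line_id == "l2"], "excluded_het")
  expect_equal(calls_ex$status[calls_ex$line_id == "l1"], "called")

  empty <- genotype_panel(toy$catalog[0, ], list(l1 = reads("l1")), toy$ref)
  expect_equal(nrow(empty), 0L)
})

test_that("the genotype matrix pivots calls with missing markers", {
  toy <- toy_locus()
  reads <- function(line, n) dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_read(toy$ref, 20L + i, "35M", name = paste0(line, "_", i))
  }))
  calls <- genotype_panel(toy$catalog,
                          list(l1 = reads("l1", 2), l2 = reads("l2", 1)),
                          toy$ref)
  m <- genotype_matrix(calls)
  expect_equal(m$l1, "14")
  expect_equal(m$l2, ".")
})

test_that("calls survive a TSV round trip", {
  toy <- toy_locus()
  reads <- dplyr::bind_rows(
    make_read(toy$ref, 20L, "35M", name = "a", line_id = "l1"),
    make_read(toy$ref, 22L, "35M", name = "b", line_id = "l1"))
  calls <- genotype_panel(toy$catalog, reads, toy$ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(back$majority_allele, calls$majority_allele)
  expect_equal(back$allele_counts, calls$allele_counts)
  expect_equal(back$status, calls$status)
})
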