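#' Score reads at catalog loci
#'
#' Evaluates every (read, locus) pair where the read's alignment footprint
#' overlaps the locus, applying the three scorability criteria: the read
#' must span the entire repeat including at least the two flanking anchor
#' bases, at least `min_flank` consecutive flanking positions adjacent to
#' the repeat must match the reference on both sides, and the read must be
#' uniquely mapped (when `require_unique`).
#'
#' The allele length is the number of read bases separating the two
#' flanking anchors, irrespective of how alignment gaps are placed inside
#' the tract: insertions between the anchors lengthen the allele, deletions
#' shorten it, and two alignments of the same read differing only in gap
#' position yield the same call. Flank runs are counted outward from the
#' repeat boundary; a mismatch, an alignment gap, or the read end
#' terminates the run, and a mismatched anchor base counts as a flank
#' mismatch (not as a missing anchor).
#'
#' @param alignments alignment tibble (see [read_alignments()]).
#' @param catalog catalog tibble; flagged loci are dropped first.
#' @param reference named character vector (or DNAStringSet) of chromosome
#'   sequences.
#' @param min_flank minimum matching flank run required on each side.
#' @param require_unique reject reads that are not uniquely mapped.
#' @return tibble of scored reads: `locus_id`, `read_name`, `line_id` (when
#'   present), `allele_length`, `flank_match_left`, `flank_match_right`,
#'   `mapq`, `read_length`, `scorable`, `rejection_reason` (one of
#'   `not_spanning`, `unanchored`, `flank_mismatch`, `not_unique`, or `NA`
#'   when scorable).
#' @export
score_reads <- function(alignments, catalog, reference, min_flank = 3L,
                        require_unique = TRUE) {
  reference <- as_reference(reference)
  loci <- catalog_pass(catalog)
  pieces <- list()
  for (ch in intersect(unique(loci$chrom), unique(alignments$chrom))) {
    lo <- loci[loci$chrom == ch, , drop = FALSE]
    al <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(lo) == 0L || nrow(al) == 0L) next
    rw <- cigar_ref_width_cpp(al$cigar)
    rread <- IRanges::IRanges(al$pos, al$pos + rw - 1L)
    # anchors: last base before the tract, first base after it (1-based)
    lanch <- lo$start
    ranch <- lo$end + 1L
    rloc <- IRanges::IRanges(pmax(lanch, 1L), ranch)
    # every read touching the anchor-to-anchor window contributes a record
    # (non-spanning reads are kept as rejections, not silently dropped)
    ov <- IRanges::findOverlaps(rloc, rread)
    li <- S4Vectors::queryHits(ov)
    ai <- S4Vectors::subjectHits(ov)
    if (!length(li)) next
    sc <- score_pairs_cpp(al$cigar[ai], al$pos[ai], al$seq[ai],
                          reference[[ch]], lanch[li], ranch[li])
    piece <- tibble(
      locus_id = lo$locus_id[li],
      read_name = al$read_name[ai],
      allele_length = ifelse(sc$status == 0L, sc$allele_length, NA_integer_),
      flank_match_left = sc$flank_left,
      flank_match_right = sc$flank_right,
      mapq = al$mapq[ai],
      read_length = if ("read_length" %in% names(al)) {
        al$read_length[ai]
      } else nchar(al$seq)[ai],
      unique = al$unique[ai],
      status = sc$status
    )
    if ("line_id" %in% names(al)) piece$line_id <- al$line_id[ai]
    pieces[[ch]] <- piece
  }
  if (!length(pieces)) {
    out <- tibble(locus_id = character(), read_name = character(),
                  allele_length = integer(), flank_match_left = integer(),
                  flank_match_right = integer(), mapq = integer(),
                  read_length = integer(), unique = logical(),
                  status = integer())
  } else {
    out <- bind_rows(pieces)
  }
  flank_ok <- out$flank_match_left >= min_flank &
    out$flank_match_right >= min_flank
  uniq_ok <- !require_unique | out$unique
  out$scorable <- out$status == 0L & flank_ok & uniq_ok
  out$rejection_reason <- dplyr::case_when(
    out$status == 1L ~ "not_spanning",
    out$status == 2L ~ "unanchored",
    !flank_ok ~ "flank_mismatch",
    !uniq_ok ~ "not_unique",
    TRUE ~ NA_character_
  )
  out$allele_length[!out$scorable & out$status != 0L] <- NA_integer_
  select(out, -all_of(c("status", "unique")))
}

#' Call per-line genotypes from scored reads
#'
#' A genotype requires at least `min_reads` scorable reads; the call is the
#' modal allele length, and internal concordance is R_major / R_total, the
#' fraction of scorable reads supporting the majority allele. An exact tie
#' for the mode yields no genotype (`ambiguous_tie`): the lines are inbred
#' and homozygous, so a tie signals error rather than heterozygosity.
#'
#' @param scored scored-read tibble from [score_reads()].
#' @param min_reads minimum scorable reads per call.
#' @return tibble with one row per (locus, line): `n_scorable`,
#'   `allele_counts` (list of named counts), `majority_allele`,
#'   `concordance`, `status`.
#' @export
call_loci <- function(scored, min_reads = 2L) {
  sc <- filter(scored, .data$scorable)
  grp <- if ("line_id" %in% names(sc)) c("locus_id", "line_id") else "locus_id"
  if (nrow(sc) == 0L) {
    out <- tibble(locus_id = character(), n_scorable = integer(),
                  allele_counts = list(), majority_allele = integer(),
                  concordance = double(), status = character())
    if ("line_id" %in% grp) out$line_id <- character()
    return(out)
  }
  sc %>%
    group_by(across(all_of(grp))) %>%
    summarise(call_one(.data$allele_length, min_reads), .groups = "drop")
}

call_one <- function(alleles, min_reads) {
  tab <- sort(table(alleles), decreasing = TRUE)
  n <- length(alleles)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (n < min_reads) {
    return(tibble(n_scorable = n, allele_counts = list(counts),
                  majority_allele = NA_integer_, concordance = NA_real_,
                  status = "insufficient_reads"))
  }
  top <- as.integer(tab[1])
  if (sum(tab == top) > 1L) {
    return(tibble(n_scorable = n, allele_counts = list(counts),
                  majority_allele = NA_integer_, concordance = NA_real_,
                  status = "ambiguous_tie"))
  }
  tibble(n_scorable = n, allele_counts = list(counts),
         majority_allele = as.integer(names(tab)[1]),
         concordance = top / n, status = "called")
}

#' Genotype a panel of lines over a catalog
#'
#' Scores and calls every (unflagged locus, line) cell. Cells on arms
#' excluded for residual heterozygosity are reported with status
#' `excluded_het` and no genotype; loci with no overlapping reads appear
#' with `n_scorable = 0` so that completeness has a well-defined
#' denominator.
#'
#' @param catalog catalog tibble.
#' @param alignments either one alignment tibble carrying a `line_id`
#'   column, or a named list of per-line alignment tibbles.
#' @param reference named character vector of chromosome sequences.
#' @param min_flank,min_reads,require_unique see [score_reads()] and
#'   [call_loci()].
#' @param excluded_arms optional tibble (`line_id`, `chrom`) of per-line
#'   excluded chromosome arms (see [exclude_heterozygous_arms()]).
#' @return calls tibble: one row per locus x line.
#' @export
genotype_panel <- function(catalog, alignments, reference, min_flank = 3L,
                           min_reads = 2L, require_unique = TRUE,
                           excluded_arms = NULL) {
  loci <- catalog_pass(catalog)
  if (is.data.frame(alignments)) {
    stopifnot("line_id" %in% names(alignments))
    alignments <- split(alignments, alignments$line_id)
  }
  if (is.null(names(alignments)) || anyDuplicated(names(alignments))) {
    stop("per-line alignments must have unique line ids", call. = FALSE)
  }
  if (nrow(loci) == 0L) {
    return(tibble(locus_id = character(), line_id = character(),
                  n_scorable = integer(), allele_counts = list(),
                  majority_allele = integer(), concordance = double(),
                  status = character()))
  }
  calls <- lapply(names(alignments), function(line) {
    al <- alignments[[line]]
    al$line_id <- line
    sc <- score_reads(al, loci, reference, min_flank = min_flank,
                      require_unique = require_unique)
    cl <- call_loci(sc, min_reads = min_reads)
    if (!"line_id" %in% names(cl)) cl$line_id <- character(0)
    missing_loci <- setdiff(loci$locus_id, cl$locus_id)
    if (length(missing_loci)) {
      cl <- bind_rows(cl, tibble(
        locus_id = missing_loci, line_id = line, n_scorable = 0L,
        allele_counts = replicate(length(missing_loci),
                                  stats::setNames(integer(0), character(0)),
                                  simplify = FALSE),
        majority_allele = NA_integer_, concordance = NA_real_,
        status = "insufficient_reads"))
    }
    cl
  })
  calls <- bind_rows(calls)
  if (!is.null(excluded_arms) && nrow(excluded_arms) > 0L) {
    ex <- loci %>%
      select(all_of(c("locus_id", "chrom"))) %>%
      inner_join(excluded_arms, by = "chrom",
                 relationship = "many-to-many") %>%
      mutate(excluded = TRUE) %>%
      select(all_of(c("locus_id", "line_id", "excluded")))
    calls <- calls %>%
      left_join(ex, by = c("locus_id", "line_id")) %>%
      mutate(
        status = if_else(!is.na(.data$excluded), "excluded_het", .data$status),
        majority_allele = if_else(!is.na(.data$excluded), NA_integer_,
                                  .data$majority_allele),
        concordance = if_else(!is.na(.data$excluded), NA_real_,
                              .data$concordance)) %>%
      select(-all_of("excluded"))
  }
  arrange(calls, .data$locus_id, .data$line_id)
}

#' Pivot calls into a loci x lines genotype matrix
#'
#' @param calls calls tibble from [genotype_panel()].
#' @param missing marker used for cells without a called genotype.
#' @return wide tibble: `locus_id` plus one column per line.
#' @export
genotype_matrix <- function(calls, missing = ".") {
  calls %>%
    mutate(allele = if_else(.data$status == "called",
                            as.character(.data$majority_allele), missing)) %>%
    select(all_of(c("locus_id", "line_id", "allele"))) %>%
    tidyr::pivot_wider(names_from = "line_id", values_from = "allele",
                       values_fill = missing) %>%
    arrange(.data$locus_id)
}

encode_counts <- function(counts) {
  vapply(counts, function(x) {
    if (!length(x)) return(".")
    paste(sprintf("%s:%d", names(x), x), collapse = ";")
  }, character(1))
}

decode_counts <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || x == ".") return(stats::setNames(integer(0), character(0)))
    parts <- strsplit(strsplit(x, ";")[[1]], ":")
    stats::setNames(as.integer(vapply(parts, `[[`, character(1), 2L)),
                    vapply(parts, `[[`, character(1), 1L))
  })
}

#' Write / read per-line calls as TSV
#'
#' @param calls calls tibble.
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$allele_counts <- encode_counts(out$allele_counts)
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  out <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(
                           locus_id = readr::col_character(),
                           line_id = readr::col_character(),
                           allele_counts = readr::col_character(),
                           status = readr::col_character()))
  out$allele_counts <- decode_counts(out$allele_counts)
  out
}
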