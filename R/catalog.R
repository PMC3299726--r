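#' Detect tandem repeats in a sequence
#'
#' Native microsatellite detector. For each unit size u in 1..`max_unit`,
#' every base is compared with the base u positions earlier; maximal-scoring
#' runs of these comparisons (match +2, mismatch -5, no indels) are located
#' with the Ruzzo-Tompa all-maximal-scoring-subsequences algorithm. The seed
#' unit is credited as matched, so with the default minimum score of 14 the
#' shortest reportable tract is 7 bases at every unit size. Overlapping and
#' nested hits are reduced with [deduplicate_hits()].
#'
#' Purity is the fraction of offset-u comparisons that match,
#' matches / (tract length - u); a perfect tract has purity 1. The unit
#' reported is the lexicographically minimal rotation of the modal u-mer.
#'
#' @param seq nucleotide string (A/C/G/T/N; N always counts as a mismatch).
#' @param chrom chromosome name used in the output.
#' @param min_score minimum alignment score (match 2, mismatch 5).
#' @param max_unit largest unit size considered.
#' @return a catalog tibble: `locus_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `unit`, `unit_length`, `purity`, `ref_length`, `score`,
#'   and logical flag columns `re_proximal`, `heterochromatic`, `low_purity`
#'   (all `FALSE`).
#' @export
find_tandem_repeats <- function(seq, chrom, min_score = 14L, max_unit = 5L) {
  seq <- toupper(as.character(seq))
  hits <- rt_scan_cpp(seq, max_unit = max_unit, min_score = min_score)
  if (nrow(hits) == 0L) return(empty_catalog())
  tract <- substring(seq, hits$start + 1L, hits$end)
  unit <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    unit[i] <- canonical_rotation(modal_unit(tract[i], hits$unit_length[i]))
  }
  loci <- tibble(
    chrom = chrom,
    start = as.integer(hits$start),
    end = as.integer(hits$end),
    unit = unit,
    unit_length = as.integer(hits$unit_length),
    purity = hits$matches / (hits$end - hits$start - hits$unit_length),
    ref_length = as.integer(hits$end - hits$start),
    score = as.integer(hits$score)
  )
  loci <- deduplicate_hits(loci)
  finish_catalog(loci)
}

empty_catalog <- function() {
  tibble(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), unit = character(), unit_length = integer(),
    purity = double(), ref_length = integer(), score = integer(),
    re_proximal = logical(), heterochromatic = logical(),
    low_purity = logical()
  )
}

finish_catalog <- function(loci) {
  loci$locus_id <- sprintf("%s_%d_%d", loci$chrom, loci$start, loci$end)
  for (fl in c("re_proximal", "heterochromatic", "low_purity")) {
    if (is.null(loci[[fl]])) loci[[fl]] <- FALSE
  }
  loci %>%
    select(all_of(c("locus_id", "chrom", "start", "end", "unit",
                    "unit_length", "purity", "ref_length", "score",
                    "re_proximal", "heterochromatic", "low_purity"))) %>%
    arrange(.data$chrom, .data$start, .data$end)
}

#' Remove redundant tandem-repeat hits
#'
#' When two hits overlap and share the same canonical unit, or one hit's
#' interval is contained in the other's, only the higher-scoring hit
#' survives. Ties break toward the longer hit, then the leftmost, then the
#' smaller unit size (a perfect tract scores identically at its unit and at
#' multiples of it over the same interval).
#'
#' @param hits catalog tibble (one or more chromosomes).
#' @return deduplicated tibble sorted by (chrom, start, end).
#' @export
deduplicate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- hits %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) dedup_one_chrom(df)) %>%
    ungroup()
  arrange(out, .data$chrom, .data$start, .data$end)
}

dedup_one_chrom <- function(df) {
  ord <- order(-df$score, -(df$end - df$start), df$start, df$unit_length)
  df <- df[ord, , drop = FALSE]
  ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  ov <- IRanges::findOverlaps(ir, ir)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keepable <- qh < sh # j conflicts with earlier (higher-priority) i
  qh <- qh[keepable]; sh <- sh[keepable]
  same_unit <- df$unit[qh] == df$unit[sh]
  contained <- (df$start[qh] <= df$start[sh] & df$end[qh] >= df$end[sh]) |
    (df$start[sh] <= df$start[qh] & df$end[sh] >= df$end[qh])
  conflict <- same_unit | contained
  qh <- qh[conflict]; sh <- sh[conflict]
  keep <- rep(TRUE, nrow(df))
  if (length(qh)) {
    ord2 <- order(sh)
    qh <- qh[ord2]; sh <- sh[ord2]
    for (k in seq_along(sh)) {
      if (keep[qh[k]]) keep[sh[k]] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

#' Parse a Tandem Repeats Finder `.dat` table
#'
#' Reads the whitespace-separated per-repeat records that follow each
#' `Sequence:` header in TRF's `.dat` output. TRF's 1-based inclusive
#' coordinates are converted to 0-based half-open; purity is TRF's
#' percent-matches field divided by 100; records with period greater than
#' `max_unit` are dropped.
#'
#' @param input path to a `.dat` file, or a character vector of lines.
#' @param chrom_names optional named character vector mapping sequence
#'   headers to chromosome names.
#' @param max_unit largest unit size retained.
#' @return catalog tibble (see [find_tandem_repeats()]).
#' @export
parse_trf_dat <- function(input, chrom_names = NULL, max_unit = 5L) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  cur <- NA_character_
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "") next
    if (grepl("^Sequence:", line)) {
      cur <- trimws(sub("^Sequence:", "", line))
      cur <- sub("\\s.*$", "", cur)
      if (!is.null(chrom_names)) {
        if (!cur %in% names(chrom_names)) {
          stop("unknown sequence header '", cur, "' at line ", ln, call. = FALSE)
        }
        cur <- chrom_names[[cur]]
      }
      next
    }
    if (!grepl("^[0-9]", line)) next # Parameters:, file headers, etc.
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) < 14L) {
      stop("malformed TRF record at line ", ln, ": expected >= 14 fields, got ",
           length(f), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[c(1:3, 6, 8)]))
    if (anyNA(num)) {
      stop("malformed TRF record at line ", ln, ": non-numeric field", call. = FALSE)
    }
    if (is.na(cur)) {
      stop("TRF record before any 'Sequence:' header at line ", ln, call. = FALSE)
    }
    period <- as.integer(num[3])
    if (period > max_unit) next
    recs[[length(recs) + 1L]] <- tibble(
      chrom = cur,
      start = as.integer(num[1]) - 1L,
      end = as.integer(num[2]),
      unit = canonical_rotation(f[14]),
      unit_length = period,
      purity = num[4] / 100,
      score = as.integer(num[5])
    )
  }
  if (!length(recs)) return(empty_catalog())
  loci <- bind_rows(recs)
  loci$ref_length <- loci$end - loci$start
  finish_catalog(loci)
}

#' Parse RepeatMasker `.out` annotations
#'
#' Reads the standard RepeatMasker `.out` dialect (three header lines, then
#' whitespace-separated columns). Intervals classed "Simple_repeat" or
#' "Low_complexity" are removed (those are the microsatellites themselves,
#' which must not mask their own catalog); remaining intervals are
#' converted to 0-based half-open coordinates.
#'
#' @param input path to a `.out` file, or a character vector of lines.
#' @param drop_classes repeat classes removed from the annotation set.
#' @return tibble with `chrom`, `start`, `end`, `repeat_class`.
#' @export
parse_repeatmasker_out <- function(input,
                                   drop_classes = c("Simple_repeat",
                                                    "Low_complexity")) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[trimws(lines) != ""]
  body <- lines[grepl("^\\s*[0-9]", lines)] # header lines never start numeric
  if (!length(body)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  repeat_class = character()))
  }
  rows <- strsplit(trimws(body), "\\s+")
  nf <- lengths(rows)
  if (any(nf < 11L)) {
    stop("malformed RepeatMasker row (", min(nf), " columns, expected >= 11) ",
         "at body line ", which(nf < 11L)[1], call. = FALSE)
  }
  out <- tibble(
    chrom = vapply(rows, `[[`, character(1), 5L),
    start = as.integer(vapply(rows, `[[`, character(1), 6L)) - 1L,
    end = as.integer(vapply(rows, `[[`, character(1), 7L)),
    repeat_class = vapply(rows, `[[`, character(1), 11L)
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("malformed RepeatMasker row: non-numeric coordinates", call. = FALSE)
  }
  base_class <- sub("/.*$", "", out$repeat_class)
  filter(out, !(base_class %in% drop_classes))
}

#' Read repetitive-element annotations from BED3+
#'
#' BED coordinates are already 0-based half-open. A fourth column, when
#' present, is taken as the repeat class and filtered like
#' [parse_repeatmasker_out()] does.
#'
#' @inheritParams parse_repeatmasker_out
#' @export
read_annotation_bed <- function(input,
                                drop_classes = c("Simple_repeat",
                                                 "Low_complexity")) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  lines <- lines[trimws(lines) != "" & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  repeat_class = character()))
  }
  rows <- strsplit(lines, "\t")
  if (any(lengths(rows) < 3L)) {
    stop("malformed BED row: fewer than 3 columns", call. = FALSE)
  }
  out <- tibble(
    chrom = vapply(rows, `[[`, character(1), 1L),
    start = as.integer(vapply(rows, `[[`, character(1), 2L)),
    end = as.integer(vapply(rows, `[[`, character(1), 3L)),
    repeat_class = vapply(rows, function(r) {
      if (length(r) >= 4L) r[[4L]] else NA_character_
    }, character(1))
  )
  filter(out, is.na(.data$repeat_class) |
           !(sub("/.*$", "", .data$repeat_class) %in% drop_classes))
}

#' Flag catalog loci near repetitive elements
#'
#' A locus lying within `distance` bases of (or overlapping) any annotation
#' interval gains the `re_proximal` flag. The gap is measured between the
#' closest interval edges; a gap less than or equal to `distance` triggers
#' the flag, so with the default a 21-base gap survives and a 20-base gap
#' does not.
#'
#' @param loci catalog tibble.
#' @param res annotation tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param distance maximum tolerated edge-to-edge gap in bases.
#' @return catalog with updated `re_proximal` flags.
#' @export
filter_near_repetitive_elements <- function(loci, res, distance = 20L) {
  if (nrow(loci) == 0L || nrow(res) == 0L) return(loci)
  loci$re_proximal <- FALSE
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    ri <- which(res$chrom == ch)
    if (!length(ri)) next
    lr <- IRanges::IRanges(loci$start[li] + 1L, loci$end[li])
    rr <- IRanges::IRanges(res$start[ri] + 1L, res$end[ri])
    nearest <- IRanges::distanceToNearest(lr, rr)
    hit <- S4Vectors::queryHits(nearest)
    d <- S4Vectors::mcols(nearest)$distance
    loci$re_proximal[li[hit[d <= distance]]] <- TRUE
  }
  loci
}

#' Flag loci on heterochromatic (or otherwise unmappable) chromosomes
#'
#' @param loci catalog tibble.
#' @param het_chroms character vector of chromosome names to exclude. The
#'   default matches the fly r5.x naming: any name ending in "Het", plus the
#'   unscaffolded bin "U".
#' @return catalog with updated `heterochromatic` flags.
#' @export
exclude_heterochromatin <- function(loci, het_chroms = NULL) {
  if (is.null(het_chroms)) {
    hot <- grepl("Het$", loci$chrom) | loci$chrom == "U"
  } else {
    hot <- loci$chrom %in% het_chroms
  }
  loci$heterochromatic <- loci$heterochromatic | hot
  loci
}

#' Flag low-purity loci
#'
#' Loci whose purity is below `min_purity` gain the `low_purity` flag; the
#' threshold is inclusive, so a locus at exactly the floor is kept.
#'
#' @param loci catalog tibble.
#' @param min_purity minimum retained purity (default 0.80).
#' @export
apply_purity_floor <- function(loci, min_purity = 0.80) {
  loci$low_purity <- loci$low_purity | (loci$purity < min_purity)
  loci
}

#' Keep only unflagged catalog loci
#'
#' @param loci catalog tibble.
#' @export
catalog_pass <- function(loci) {
  filter(loci, !.data$re_proximal, !.data$heterochromatic, !.data$low_purity)
}

#' Write / read a catalog as TSV
#'
#' The three flag columns are serialised into a single comma-separated
#' `flags` column ("." when unflagged); `read_catalog()` restores them, so
#' write-then-read is the identity.
#'
#' @param loci catalog tibble.
#' @param path output path.
#' @export
write_catalog <- function(loci, path) {
  out <- loci
  flags <- cbind(
    ifelse(out$re_proximal, "re_proximal", NA),
    ifelse(out$heterochromatic, "heterochromatic", NA),
    ifelse(out$low_purity, "low_purity", NA)
  )
  out$flags <- apply(flags, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ",") else "."
  })
  out <- select(out, -all_of(c("re_proximal", "heterochromatic", "low_purity")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           unit = readr::col_character(),
                           flags = readr::col_character()))
  out$re_proximal <- grepl("re_proximal", out$flags)
  out$heterochromatic <- grepl("heterochromatic", out$flags)
  out$low_purity <- grepl("low_purity", out$flags)
  out$flags <- NULL
  finish_catalog(out)
}

#' Write a catalog as BED6
#'
#' @param loci catalog tibble.
#' @param path output path.
#' @export
write_catalog_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start, loci$end, loci$locus_id,
                    pmin(loci$score, 1000L), "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a filtered catalog from a reference
#'
#' Convenience wrapper over the catalog pipeline: detect (or parse) repeats,
#' deduplicate, then apply the repetitive-element proximity, heterochromatin
#' and purity filters. Filter order does not affect the flagged set.
#'
#' @param reference named character vector / DNAStringSet of chromosomes, or
#'   a FASTA path.
#' @param trf_dat optional TRF `.dat` input; when supplied the native
#'   detector is not run.
#' @param repeatmasker optional RepeatMasker `.out` (or BED) input.
#' @param re_distance proximity threshold in bases.
#' @param het_chroms see [exclude_heterochromatin()].
#' @param min_purity see [apply_purity_floor()].
#' @return catalog tibble with flags set.
#' @export
build_catalog <- function(reference, trf_dat = NULL, repeatmasker = NULL,
                          re_distance = 20L, het_chroms = NULL,
                          min_purity = 0.80) {
  if (is.null(trf_dat)) {
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference)) {
      reference <- read_reference(reference)
    }
    reference <- as_reference(reference)
    loci <- bind_rows(lapply(names(reference), function(ch) {
      find_tandem_repeats(reference[[ch]], ch)
    }))
    if (nrow(loci) == 0L) loci <- empty_catalog()
  } else {
    loci <- parse_trf_dat(trf_dat)
    loci <- deduplicate_hits(loci)
    loci <- finish_catalog(loci)
  }
  if (!is.null(repeatmasker)) {
    lines1 <- if (length(repeatmasker) == 1L && file.exists(repeatmasker)) {
      readLines(repeatmasker)
    } else repeatmasker
    is_bed <- all(grepl("\t", head(lines1[trimws(lines1) != ""], 5L)))
    res <- if (is_bed) read_annotation_bed(lines1) else parse_repeatmasker_out(lines1)
    loci <- filter_near_repetitive_elements(loci, res, distance = re_distance)
  }
  loci <- exclude_heterochromatin(loci, het_chroms)
  loci <- apply_purity_floor(loci, min_purity)
  loci
}
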