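#' Read reference-mapped reads into an alignment tibble
#'
#' Loads a coordinate-mapped SAM or BAM file into the flat alignment table
#' the genotyper consumes. Text SAM is converted with [Rsamtools::asBam()]
#' on the fly. Unmapped records are dropped. Unique mapping is
#' operationalised as: MapQ greater than zero and no alternative-hit
#' annotation on the record (BWA's `XT:A:R` / `X1 > 0` / an `XA` list all
#' mark a read non-unique).
#'
#' @param path SAM or BAM file.
#' @param line_id optional line identifier attached to every read.
#' @return tibble with `read_name`, `chrom`, `pos` (1-based leftmost),
#'   `mapq`, `cigar`, `seq`, `unique`, `read_length` (and `line_id`).
#' @export
read_alignments <- function(path, line_id = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("XT", "X1", "XA"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  xt <- x$tag$XT %||% rep(NA_character_, length(x$pos))
  x1 <- x$tag$X1 %||% rep(NA_integer_, length(x$pos))
  xa <- x$tag$XA %||% rep(NA_character_, length(x$pos))
  out <- tibble(
    read_name = x$qname[keep],
    chrom = as.character(x$rname)[keep],
    pos = x$pos[keep],
    mapq = x$mapq[keep],
    cigar = x$cigar[keep],
    seq = as.character(x$seq)[keep],
    unique = x$mapq[keep] > 0L &
      (is.na(xt[keep]) | xt[keep] != "R") &
      (is.na(x1[keep]) | x1[keep] == 0L) &
      is.na(xa[keep])
  )
  out$read_length <- nchar(out$seq)
  if (!is.null(line_id)) out$line_id <- line_id
  out
}

#' Write an alignment tibble as text SAM
#'
#' Emits a minimal single-end SAM with `@SQ` headers; the `unique` column is
#' round-tripped through the `XT:A:U`/`XT:A:R` tag.
#'
#' @param alignments alignment tibble (see [read_alignments()]).
#' @param path output path (should end in `.sam`).
#' @param seqlengths named integer vector of chromosome lengths.
#' @export
write_sam <- function(alignments, path, seqlengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  a <- arrange(alignments, .data$chrom, .data$pos)
  writeLines(sprintf(
    "%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXT:A:%s",
    a$read_name, a$chrom, a$pos, a$mapq, a$cigar, a$seq,
    strrep("I", nchar(a$seq)), ifelse(a$unique, "U", "R")), con)
  invisible(path)
}
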