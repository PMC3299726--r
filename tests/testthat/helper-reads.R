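# A tiny hand-built locus for genotyper unit tests: 30 bases of flank, a
# 14-base AC tract, 30 bases of flank. Locus: start = 30, end = 44.
toy_locus <- function() {
  set.seed(421)
  left <- plant_repeat("AC", 14L, flank = 27L) # 27 + 3 guard = 30 flank
  catalog <- tibble::tibble(
    locus_id = "c_30_44", chrom = "c", start = 30L, end = 44L,
    unit = "AC", unit_length = 2L, purity = 1, ref_length = 14L,
    score = 28L, re_proximal = FALSE, heterochromatic = FALSE,
    low_purity = FALSE)
  list(ref = c(c = left$seq), catalog = catalog)
}

# build a read tibble row aligned at `pos` (1-based) with an explicit cigar;
# unless `seq` is given, the query is synthesised from the reference: M
# copies reference bases, D skips them, I inserts bases from `ins`
make_read <- function(ref, pos, cigar, seq = NULL, ins = "ACAC", mapq = 37L,
                      unique = TRUE, name = "r1", line_id = NULL) {
  if (is.null(seq)) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    rp <- pos
    parts <- character(0)
    ins_pool <- strrep(ins, 50L)
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        parts <- c(parts, substr(ref[[1]], rp, rp + len - 1L))
        rp <- rp + len
      } else if (type %in% c("D", "N")) {
        rp <- rp + len
      } else if (type %in% c("I", "S")) {
        parts <- c(parts, substr(ins_pool, 1L, len))
      }
    }
    seq <- paste(parts, collapse = "")
  }
  out <- tibble::tibble(read_name = name, chrom = names(ref)[1], pos = pos,
                        mapq = mapq, cigar = cigar, seq = seq,
                        unique = unique, read_length = nchar(seq))
  if (!is.null(line_id)) out$line_id <- line_id
  out
}

# scored-read row(s) for one read against the toy locus
score_toy <- function(reads, min_flank = 3L, require_unique = TRUE,
                      toy = toy_locus()) {
  score_reads(reads, toy$catalog, toy$ref, min_flank = min_flank,
              require_unique = require_unique)
}
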