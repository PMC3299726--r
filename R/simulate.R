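#' Configuration for the synthetic microsatellite data generator
#'
#' Bundles the generative assumptions the analyses are tested against: a
#' multi-chromosome reference with planted perfect and imperfect repeats of
#' unit size 1-5 and a right-skewed tract-length distribution (most loci
#' shorter than 23 bases, median near 11); a panel of homozygous inbred
#' lines whose repeat alleles evolved by (mostly) whole-unit stepwise
#' mutation with intensity increasing in tract length and purity and
#' decreasing in unit size; and single-end reads with substitution errors,
#' unit-slippage errors concentrated in homopolymers, and a controllable
#' fraction of mismapped reads.
#'
#' @param seed RNG seed; the seed fully determines every output.
#' @param n_chromosomes,n_loci reference layout; loci are spread evenly
#'   over chromosomes and unit sizes in `units`.
#' @param units unit sizes planted.
#' @param length_geom_p geometric tail parameter of tract length
#'   (length = 7 + Geom(p)); the default puts ~90% of loci below 23 bases.
#' @param max_length longest planted tract.
#' @param frac_imperfect fraction of loci given internal interruptions
#'   (target purity ~0.85-0.97); tracts shorter than 15 bases stay perfect.
#' @param n_lines inbred lines in the panel.
#' @param intensity expected mutation steps per line for a pure 10-base
#'   mononucleotide-equivalent tract; per-locus rate scales as
#'   length x purity / (10 x unit size).
#' @param whole_unit_fraction probability that a mutation step is a whole
#'   repeat unit; the remainder are 1-2 base events that are not unit
#'   multiples (mononucleotides mutate in whole units by definition).
#' @param threshold_by_unit named vector (units "1".."5") of tract lengths
#'   below which whole-unit slippage is switched off.
#' @param read_lengths,read_mix read lengths emitted and their coverage
#'   shares.
#' @param coverage mean per-line sequencing depth.
#' @param sub_error per-base substitution error rate; `error_ramp` > 0
#'   weights errors toward the 3' end of reads (later cycles).
#' @param slip_rate probability that a read traversing a homopolymer tract
#'   gains/loses one unit; for units >= 2 the rate is multiplied by
#'   `slip_unit_factor`.
#' @param mismap_frac fraction of tract-spanning reads relocated to a
#'   different same-unit locus with degraded MapQ.
#' @param mapq,mismap_mapq MapQ assigned to well-mapped / mismapped reads.
#' @param loci_spec optional tibble (`unit_length`, `ref_length`) fixing the
#'   exact loci planted (all perfect) instead of random draws; rows are
#'   spread over chromosomes in order.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L, n_loci = 200L,
                       units = 1:5, length_geom_p = 0.134,
                       max_length = 40L, frac_imperfect = 0.15,
                       n_lines = 20L, intensity = 0.3,
                       whole_unit_fraction = 1.0,
                       threshold_by_unit = c(`1` = 0L, `2` = 0L, `3` = 0L,
                                             `4` = 0L, `5` = 0L),
                       read_lengths = 75L, read_mix = NULL, coverage = 20,
                       sub_error = 0, error_ramp = 0, slip_rate = 0,
                       slip_unit_factor = 0.1, mismap_frac = 0,
                       mapq = 37L, mismap_mapq = 20L, loci_spec = NULL) {
  read_mix <- read_mix %||% rep(1 / length(read_lengths), length(read_lengths))
  stopifnot(length(read_mix) == length(read_lengths),
            all(c(sub_error, slip_rate, mismap_frac,
                  whole_unit_fraction) >= 0),
            all(c(sub_error, slip_rate, mismap_frac,
                  whole_unit_fraction) <= 1),
            coverage > 0, n_lines >= 1, n_loci >= 0)
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    n_loci = as.integer(n_loci), units = as.integer(units),
    length_geom_p = length_geom_p, max_length = as.integer(max_length),
    frac_imperfect = frac_imperfect, n_lines = as.integer(n_lines),
    intensity = intensity, whole_unit_fraction = whole_unit_fraction,
    threshold_by_unit = threshold_by_unit,
    read_lengths = as.integer(read_lengths),
    read_mix = read_mix / sum(read_mix), coverage = coverage,
    sub_error = sub_error, error_ramp = error_ramp, slip_rate = slip_rate,
    slip_unit_factor = slip_unit_factor, mismap_frac = mismap_frac,
    mapq = as.integer(mapq), mismap_mapq = as.integer(mismap_mapq),
    loci_spec = loci_spec
  ), class = "sim_config")
}

# a primitive unit: no rotation of it has a smaller period
random_unit <- function(u) {
  repeat {
    unit <- paste(sample(BASES, u, replace = TRUE), collapse = "")
    if (u == 1L) return(unit)
    primitive <- TRUE
    for (p in seq_len(u - 1L)) {
      if (u %% p == 0L &&
          unit == substr(strrep(substr(unit, 1L, p), u), 1L, u)) {
        primitive <- FALSE
        break
      }
    }
    if (primitive) return(unit)
  }
}

make_tract <- function(unit, len, imperfect) {
  u <- nchar(unit)
  tr <- substr(strrep(unit, ceiling(len / u) + 1L), 1L, len)
  if (imperfect && len >= 15L) {
    # interruptions kept away from the tract ends so boundaries stay clean
    slots <- (u + 3L):(len - u - 2L)
    n_int <- max(1L, round(stats::runif(1, 0.01, 0.06) * len))
    at <- sample(slots, min(n_int, length(slots)))
    for (p in at) {
      old <- substr(tr, p, p)
      substr(tr, p, p) <- sample(setdiff(BASES, old), 1L)
    }
  }
  tr
}

# unit sizes whose hits can contain a planted tract of period u within 1..5
dangerous_units <- function(u) seq(u, 5L, by = u)

# guard bases adjacent to a tract: each of the three flanking positions is
# chosen to mismatch the base one dangerous-unit offset into the tract, so
# no detector run of a containing unit size can extend across the boundary
guard_bases <- function(tract, u, side) {
  tr <- strsplit(tract, "")[[1]]
  n <- length(tr)
  g <- character(3L)
  for (k in 1:3) {
    banned <- character(0)
    for (du in dangerous_units(u)) {
      off <- du - k # offset into the tract (or earlier guard base)
      b <- if (off >= 0L) {
        if (side == "left") tr[off + 1L] else tr[n - off]
      } else {
        g[-off] # previously chosen guard base
      }
      banned <- c(banned, b)
    }
    g[k] <- sample(setdiff(BASES, banned), 1L)
  }
  if (side == "left") paste(rev(g), collapse = "") else paste(g, collapse = "")
}

#' Simulate a reference genome with planted repeats
#'
#' Plants repeats with known coordinates, units and purity into random
#' background sequence, separated by at least twice the longest read length
#' of unique flank. Three guard bases on each side of every tract, plus a
#' detector check with chromosome redraw, guarantee that each planted
#' perfect repeat is the maximal repeat at its position, so the native
#' detector reports it at exactly the planted coordinates.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (named character vector), `loci` (truth
#'   catalog tibble) and `config`. Call [set.seed()] (or use
#'   [simulate_dataset()]) for reproducibility.
#' @export
simulate_reference <- function(config = sim_config()) {
  n_chr <- config$n_chromosomes
  spec <- config$loci_spec
  n_total <- if (is.null(spec)) config$n_loci else nrow(spec)
  per_chr <- diff(round(seq(0, n_total, length.out = n_chr + 1L)))
  spec_off <- cumsum(c(0L, per_chr))
  spacing <- 2L * max(config$read_lengths)
  seqs <- stats::setNames(character(n_chr), paste0("chr", seq_len(n_chr)))
  truth <- list()
  for (ci in seq_len(n_chr)) {
    ch <- names(seqs)[ci]
    n_here <- per_chr[ci]
    for (attempt in 1:25) {
      if (is.null(spec)) {
        units <- if (n_here > 0) {
          sample(rep(config$units, length.out = n_here))
        } else integer(0)
        lens <- pmin(7L + stats::rgeom(n_here, config$length_geom_p),
                     config$max_length)
        lens <- pmax(lens, units + 2L)
        imperf <- stats::runif(n_here) < config$frac_imperfect
      } else {
        rows <- spec[seq_len(n_here) + spec_off[ci], ]
        units <- as.integer(rows$unit_length)
        lens <- as.integer(rows$ref_length)
        imperf <- rep(FALSE, n_here)
      }
      pieces <- character(0)
      at <- 0L # current chromosome length
      rows <- vector("list", n_here)
      ok <- TRUE
      for (i in seq_len(n_here)) {
        unit <- random_unit(units[i])
        tr <- make_tract(unit, lens[i], imperf[i])
        gap <- random_dna(spacing + stats::rpois(1, 20))
        gl <- guard_bases(tr, units[i], "left")
        gr <- guard_bases(tr, units[i], "right")
        start0 <- at + nchar(gap) + 3L
        pieces <- c(pieces, gap, gl, tr, gr)
        at <- start0 + nchar(tr) + 3L
        rows[[i]] <- tibble(
          chrom = ch, start = start0, end = start0 + nchar(tr),
          unit = canonical_rotation(modal_unit(tr, units[i])),
          unit_length = units[i],
          purity = if (nchar(tr) > units[i]) {
            count_unit_matches(tr, units[i]) / (nchar(tr) - units[i])
          } else 1,
          ref_length = nchar(tr), score = NA_integer_)
      }
      pieces <- c(pieces, random_dna(spacing + stats::rpois(1, 20)))
      chrom_seq <- paste(pieces, collapse = "")
      loci <- if (n_here > 0) bind_rows(rows) else NULL
      # verify perfect planted loci are reported exactly; redraw otherwise
      if (!is.null(loci) && any(loci$purity == 1)) {
        det <- find_tandem_repeats(chrom_seq, ch)
        want <- loci[loci$purity == 1, ]
        hitkey <- paste(det$start, det$end, det$unit_length)
        exact <- all(paste(want$start, want$end, want$unit_length) %in% hitkey)
        if (!exact) next
      }
      seqs[[ci]] <- chrom_seq
      if (!is.null(loci)) truth[[ci]] <- loci
      break
    }
    if (seqs[[ci]] == "") {
      stop("failed to assemble chromosome ", ch, " with maximal planted loci",
           call. = FALSE)
    }
  }
  loci <- if (length(truth)) finish_catalog(bind_rows(truth)) else empty_catalog()
  loci$score <- 2L * loci$ref_length # perfect-tract detector score scale
  list(sequences = seqs, loci = loci, config = config)
}

#' Simulate a panel of inbred-line alleles under stepwise mutation
#'
#' Each line draws each locus allele as the reference length plus a sum of
#' signed mutation steps. Step counts are Poisson with intensity increasing
#' in tract length and purity and decreasing in unit size; a step is a
#' whole repeat unit with probability `whole_unit_fraction`, otherwise a
#' 1-2 base event that is not a unit multiple. Whole-unit slippage can be
#' restricted to tracts at or above a per-unit threshold length.
#'
#' @param reference result of [simulate_reference()].
#' @param config a [sim_config()] (defaults to the reference's).
#' @return tibble: `locus_id`, `line_id`, `true_allele`, `delta`.
#' @export
simulate_panel <- function(reference, config = reference$config) {
  loci <- reference$loci
  n_loci <- nrow(loci)
  lines <- sprintf("line%02d", seq_len(config$n_lines))
  thr <- config$threshold_by_unit[as.character(loci$unit_length)]
  thr[is.na(thr)] <- 0L
  lambda <- config$intensity * pmin(loci$ref_length, 60L) * loci$purity /
    (10 * loci$unit_length)
  p_wu <- ifelse(loci$unit_length == 1L, 1, config$whole_unit_fraction)
  lam_wu <- lambda * p_wu * (loci$ref_length >= thr)
  lam_nu <- lambda * (1 - p_wu)
  nu_sizes <- list(`1` = integer(0), `2` = 1L, `3` = 1:2, `4` = 1:2, `5` = 1:2)
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    n_wu <- stats::rpois(n_loci, lam_wu)
    n_nu <- stats::rpois(n_loci, lam_nu)
    delta <- integer(n_loci)
    hot <- which(n_wu + n_nu > 0L)
    for (i in hot) {
      u <- loci$unit_length[i]
      d_wu <- if (n_wu[i]) sum(sample(c(-u, u), n_wu[i], replace = TRUE)) else 0L
      d_nu <- if (n_nu[i]) {
        sizes <- nu_sizes[[as.character(u)]]
        sum(sample(c(-1L, 1L), n_nu[i], replace = TRUE) *
              sample(sizes, n_nu[i], replace = TRUE))
      } else 0L
      delta[i] <- d_wu + d_nu
    }
    # a tract cannot shrink below one unit: bounce back in whole units so
    # clamping never breaks the step-size arithmetic
    allele <- loci$ref_length + delta
    lo <- pmax(loci$unit_length, 2L)
    short <- allele < lo
    if (any(short)) {
      allele[short] <- allele[short] +
        ceiling((lo[short] - allele[short]) / loci$unit_length[short]) *
        loci$unit_length[short]
    }
    out[[li]] <- tibble(locus_id = loci$locus_id, line_id = lines[li],
                        true_allele = as.integer(allele),
                        delta = as.integer(allele - loci$ref_length))
  }
  bind_rows(out)
}

# mutate a tract string to the target allele length by inserting unit
# copies (or deleting bases) just after the first unit
retract <- function(tr, unit, allele) {
  u <- nchar(unit)
  len <- nchar(tr)
  d <- allele - len
  if (d == 0L) return(tr)
  if (d > 0L) {
    ins <- substr(strrep(unit, ceiling(d / u) + 1L), 1L, d)
    return(paste0(substr(tr, 1L, u), ins, substr(tr, u + 1L, len)))
  }
  paste0(substr(tr, 1L, u), substr(tr, u + 1L - d, len))
}

#' Simulate reference-mapped reads for a panel
#'
#' Emits reads pre-aligned to the reference coordinate system, simulating
#' the output of a mapping step rather than the mapper itself. Reads are
#' drawn uniformly along each line's mutated chromosome; a read that fully
#' spans a mutated tract carries a CIGAR whose insertion/deletion is placed
#' at a uniformly random position inside the tract (exercising the
#' gap-invariance of the allele-length rule), substitution errors are
#' i.i.d. (or ramped toward the read end), slippage errors of one unit are
#' injected at spanning traversals of homopolymer tracts, and a configured
#' fraction of spanning reads is relocated to a different same-unit locus
#' with degraded MapQ, so flank mismatches arise naturally.
#'
#' @param reference result of [simulate_reference()].
#' @param panel tibble from [simulate_panel()].
#' @param config a [sim_config()].
#' @return alignment tibble for all lines with truth columns
#'   `origin_locus`, `read_allele` (tract length carried by the read, NA
#'   for non-spanning reads) and `mismapped`.
#' @export
simulate_reads <- function(reference, panel, config = reference$config) {
  all_loci <- reference$loci
  lines <- unique(panel$line_id)
  out <- vector("list", 0L)
  for (line in lines) {
    pl <- panel[panel$line_id == line, ]
    for (ch in names(reference$sequences)) {
      lo <- all_loci[all_loci$chrom == ch, ]
      refseq <- reference$sequences[[ch]]
      reads <- sim_reads_one(refseq, ch, lo, pl, config, line)
      if (!is.null(reads)) out[[length(out) + 1L]] <- reads
    }
  }
  reads <- bind_rows(out)
  if (config$mismap_frac > 0 && nrow(reads) > 0L) {
    reads <- apply_mismap(reads, all_loci, config,
                          nchar(reference$sequences))
  }
  reads
}

sim_reads_one <- function(refseq, ch, lo, pl, config, line) {
  lo <- arrange(lo, .data$start)
  alle <- pl$true_allele[match(lo$locus_id, pl$locus_id)]
  alle[is.na(alle)] <- lo$ref_length[is.na(alle)]
  n_loci <- nrow(lo)
  # build the line's mutated chromosome and the tract coordinate tables
  segs <- character(2L * n_loci + 1L)
  ms <- me <- integer(n_loci)
  cumdel <- integer(n_loci) # total delta strictly before locus i
  prev_ref_end <- 0L
  at <- 0L
  running_delta <- 0L
  for (i in seq_len(n_loci)) {
    gap <- substr(refseq, prev_ref_end + 1L, lo$start[i])
    tr <- substr(refseq, lo$start[i] + 1L, lo$end[i])
    mtr <- retract(tr, substr(tr, 1L, lo$unit_length[i]), alle[i])
    segs[2L * i - 1L] <- gap
    segs[2L * i] <- mtr
    ms[i] <- at + nchar(gap) + 1L
    me[i] <- ms[i] + nchar(mtr) - 1L
    cumdel[i] <- running_delta
    running_delta <- running_delta + (nchar(mtr) - nchar(tr))
    at <- me[i]
    prev_ref_end <- lo$end[i]
  }
  segs[2L * n_loci + 1L] <- substr(refseq, prev_ref_end + 1L, nchar(refseq))
  mut <- paste(segs, collapse = "")
  mutlen <- nchar(mut)
  reflen <- nchar(refseq)

  group_reads <- vector("list", length(config$read_lengths))
  for (gi in seq_along(config$read_lengths)) {
    rl <- config$read_lengths[gi]
    n_reads <- round(config$coverage * config$read_mix[gi] * mutlen / rl)
    if (n_reads == 0L || mutlen <= rl) next
    s <- sample.int(mutlen - rl + 1L, n_reads, replace = TRUE)
    e <- s + rl - 1L
    seqv <- substring(mut, s, e)
    # the single candidate tract a read could span (spacing >> read length)
    i0 <- if (n_loci > 0L) findInterval(e, ms) else integer(n_reads)
    spans <- i0 >= 1L & i0 <= n_loci
    spans[spans] <- ms[i0[spans]] > s[spans] & me[i0[spans]] < e[spans]
    cigar <- rep(paste0(rl, "M"), n_reads)
    pos <- mut_to_ref_pos(s, ms, me, cumdel, lo, rl, reflen)
    allele_read <- rep(NA_integer_, n_reads)
    origin <- rep(NA_character_, n_reads)

    sp <- which(spans)
    if (length(sp)) {
      i <- i0[sp]
      a <- me[i] - ms[i] + 1L
      r <- lo$ref_length[i]
      left <- ms[i] - s[sp]
      # slippage: one unit gained/lost during tract traversal
      p_slip <- config$slip_rate *
        ifelse(lo$unit_length[i] == 1L, 1, config$slip_unit_factor)
      slip <- stats::runif(length(sp)) < p_slip
      sdelta <- ifelse(slip, sample(c(-1L, 1L), length(sp), replace = TRUE) *
                         lo$unit_length[i], 0L)
      a_read <- pmax(a + sdelta, lo$unit_length[i])
      right <- rl - left - a_read
      bad <- right < 1L | (ms[i] - 1L + a_read + right) > mutlen
      a_read[bad] <- a[bad] # drop the slip rather than the read
      right <- rl - left - a_read
      slipped <- which(a_read != a)
      if (length(slipped)) {
        k <- sp[slipped]; ii <- i0[k]
        mtr_new <- vapply(seq_along(k), function(z) {
          tr <- substring(mut, ms[ii[z]], me[ii[z]])
          retract(tr, substr(tr, 1L, lo$unit_length[ii[z]]),
                  a_read[slipped[z]])
        }, character(1))
        seqv[k] <- paste0(
          substring(mut, s[k], ms[ii] - 1L), mtr_new,
          substring(mut, me[ii] + 1L, me[ii] + right[slipped]))
      }
      dr <- a_read - r
      pos[sp] <- s[sp] - cumdel[i]
      g_ins <- floor(stats::runif(length(sp)) * (r + 1L))
      g_del <- floor(stats::runif(length(sp)) * (a_read + 1L))
      cigar[sp] <- ifelse(
        dr == 0L, paste0(rl, "M"),
        ifelse(dr > 0L,
               paste0(left + g_ins, "M", dr, "I",
                      (r - g_ins) + right, "M"),
               paste0(left + g_del, "M", -dr, "D",
                      (a_read - g_del) + right, "M")))
      allele_read[sp] <- a_read
      origin[sp] <- lo$locus_id[i]
    }
    tib <- tibble(
      read_name = sprintf("%s_%s_%d_%d", line, ch, gi, seq_len(n_reads)),
      chrom = ch, pos = as.integer(pos), mapq = config$mapq,
      cigar = cigar, seq = seqv, unique = TRUE,
      read_length = rl, line_id = line,
      origin_locus = origin, read_allele = allele_read, mismapped = FALSE)
    group_reads[[gi]] <- tib
  }
  reads <- bind_rows(group_reads)
  if (nrow(reads) && config$sub_error > 0) {
    reads$seq <- apply_sub_errors(reads$seq, config)
  }
  reads
}

# map mutated-chromosome positions back to reference positions (positions
# inside a mutated tract clamp to the tract's reference footprint)
mut_to_ref_pos <- function(s, ms, me, cumdel, lo, rl, reflen) {
  if (!length(ms)) return(pmin(s, reflen - rl + 1L))
  piece <- findInterval(s, ms) # 0 = before first tract
  pos <- integer(length(s))
  before <- piece == 0L
  pos[before] <- s[before]
  for (i in unique(piece[piece > 0L])) {
    k <- which(piece == i)
    inside <- s[k] <= me[i]
    ref_tract_start <- lo$start[i] + 1L
    pos[k[inside]] <- ref_tract_start +
      pmin(s[k[inside]] - ms[i], lo$ref_length[i] - 1L)
    pos[k[!inside]] <- s[k[!inside]] - (cumdel[i] +
      (me[i] - ms[i] + 1L) - lo$ref_length[i])
  }
  pmax(pmin(pos, reflen - rl + 1L), 1L)
}

apply_sub_errors <- function(seqs, config) {
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, config$sub_error)
  hot <- which(n_err > 0L)
  for (i in hot) {
    w <- if (config$error_ramp > 0) {
      1 + config$error_ramp * (seq_len(rl[i]) / rl[i])
    } else NULL
    at <- sample.int(rl[i], n_err[i], prob = w)
    for (p in at) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1L)
    }
  }
  seqs
}

apply_mismap <- function(reads, loci, config, seqlen) {
  sp <- which(!is.na(reads$origin_locus))
  if (!length(sp)) return(reads)
  n_mm <- round(config$mismap_frac * length(sp))
  if (n_mm == 0L) return(reads)
  pick <- sample(sp, n_mm)
  lidx <- match(reads$origin_locus[pick], loci$locus_id)
  rw <- cigar_ref_width_cpp(reads$cigar[pick])
  for (z in seq_along(pick)) {
    i <- lidx[z]
    pool <- which(loci$unit_length == loci$unit_length[i] &
                    loci$locus_id != loci$locus_id[i])
    if (!length(pool)) next
    j <- sample(pool, 1L)
    k <- pick[z]
    left <- loci$start[i] - reads$pos[k] + 1L # anchor query offset
    newpos <- loci$start[j] - left + 1L
    if (newpos < 1L ||
        newpos + rw[z] - 1L > seqlen[[loci$chrom[j]]]) next
    reads$chrom[k] <- loci$chrom[j]
    reads$pos[k] <- newpos
    reads$mapq[k] <- config$mismap_mapq
    reads$mismapped[k] <- TRUE
  }
  reads
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [simulate_reference()], [simulate_panel()] and [simulate_reads()]
#' under a single seed, so the result is fully reproducible.
#'
#' @param config a [sim_config()].
#' @return list: `reference` (sequences + truth catalog), `catalog` (truth
#'   catalog tibble), `panel`, `alignments`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  ref <- simulate_reference(config)
  panel <- simulate_panel(ref, config)
  alignments <- simulate_reads(ref, panel, config)
  list(reference = ref, catalog = ref$loci, panel = panel,
       alignments = alignments, config = config)
}

#' Write a simulated dataset to files
#'
#' Emits the reference FASTA, the truth catalog (TSV + BED), the per-line
#' truth panel, one SAM per line, and a JSON manifest embedding the config
#' (including the seed) and a config hash, so reruns are verifiable.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the files written.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$reference$sequences), fa)
  cat_tsv <- file.path(dir, "catalog.tsv")
  write_catalog(dataset$catalog, cat_tsv)
  cat_bed <- file.path(dir, "catalog.bed")
  write_catalog_bed(dataset$catalog, cat_bed)
  panel_tsv <- file.path(dir, "truth_panel.tsv")
  readr::write_tsv(dataset$panel, panel_tsv)
  seqlen <- nchar(dataset$reference$sequences)
  sams <- vapply(unique(dataset$alignments$line_id), function(line) {
    f <- file.path(dir, paste0(line, ".sam"))
    write_sam(dataset$alignments[dataset$alignments$line_id == line,
                                 c("read_name", "chrom", "pos", "mapq",
                                   "cigar", "seq", "unique")],
              f, seqlen)
    f
  }, character(1))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(dataset$config),
         config_hash = rlang::hash(unclass(dataset$config)),
         files = c(reference = fa, catalog = cat_tsv, bed = cat_bed,
                   panel = panel_tsv, sams = unname(sams))),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(reference = fa, catalog = cat_tsv, bed = cat_bed,
                 panel = panel_tsv, sams = sams, manifest = manifest))
}
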