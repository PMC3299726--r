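#' Build per-locus allele spectra across a panel
#'
#' For each locus called in at least two lines, records the modal allele
#' length across lines (ties break toward the smaller allele), the number
#' of distinct alleles, and the deltas (allele - modal allele) of the
#' non-modal allele observations. Deltas are measured against the
#' population's modal allele, not the reference allele.
#'
#' @param calls calls tibble from [genotype_panel()].
#' @return tibble: `locus_id`, `n_lines_called`, `modal_allele`,
#'   `n_distinct_alleles`, `deltas` (list column, zero deltas excluded).
#' @export
build_allele_spectra <- function(calls) {
  x <- filter(calls, .data$status == "called")
  x %>%
    group_by(.data$locus_id) %>%
    summarise(spectrum_one(.data$majority_allele), .groups = "drop") %>%
    filter(.data$n_lines_called >= 2L)
}

spectrum_one <- function(alleles) {
  tab <- table(alleles)
  top <- max(tab)
  modal <- min(as.integer(names(tab)[tab == top])) # tie -> smaller allele
  deltas <- alleles[alleles != modal] - modal
  tibble(n_lines_called = length(alleles), modal_allele = modal,
         n_distinct_alleles = length(tab), deltas = list(as.integer(deltas)))
}

#' Mean number of distinct alleles by length bin
#'
#' Bins loci by their modal allele length (the population's most frequent
#' allele), within unit-size or purity-class groups, and reports the mean
#' number of distinct alleles per bin. Bins holding fewer than `min_bin`
#' loci are suppressed. Mononucleotides are excluded (unit sizes 2-5 only),
#' as sequencing error dominates their apparent variation.
#'
#' @param spectra spectra tibble from [build_allele_spectra()].
#' @param catalog catalog tibble.
#' @param group_by "unit_length" or "purity_class".
#' @param min_bin minimum loci per reported bin.
#' @param purity_breaks cut points for purity classes when grouping by
#'   purity.
#' @return tibble: `group`, `length` (modal allele length), `n_loci`,
#'   `mean_alleles`.
#' @export
mean_alleles_by_bin <- function(spectra, catalog, group_by = "unit_length",
                                min_bin = 25L,
                                purity_breaks = c(0, 0.9, 0.98, 1)) {
  x <- spectra %>%
    left_join(select(catalog, all_of(c("locus_id", "unit_length", "purity"))),
              by = "locus_id") %>%
    filter(.data$unit_length >= 2L, .data$unit_length <= 5L)
  x$group <- if (group_by == "purity_class") {
    cut(x$purity, breaks = purity_breaks, include.lowest = TRUE)
  } else {
    x[[group_by]]
  }
  x %>%
    group_by(.data$group, length = .data$modal_allele) %>%
    summarise(n_loci = n(), mean_alleles = mean(.data$n_distinct_alleles),
              .groups = "drop") %>%
    filter(.data$n_loci >= min_bin) %>%
    arrange(.data$group, .data$length)
}

#' In-phase (whole-unit) variation by repeat length
#'
#' For units 2-5, the percentage of non-modal alleles whose length
#' difference from the population's modal allele is an exact multiple of
#' the unit length, per unit size and modal-length bin. By default only
#' uninterrupted (purity 1) repeats are used, mirroring how stepwise
#' behaviour is normally assessed.
#'
#' @param spectra spectra tibble.
#' @param catalog catalog tibble.
#' @param pure_only restrict to purity-1 loci.
#' @param bin_width length-bin width in bases.
#' @return tibble: `unit_length`, `length_bin`, `n_variant_alleles`,
#'   `n_in_phase`, `percent_in_phase`.
#' @export
in_phase_analysis <- function(spectra, catalog, pure_only = TRUE,
                              bin_width = 1L) {
  x <- spectra %>%
    left_join(select(catalog, all_of(c("locus_id", "unit_length", "purity"))),
              by = "locus_id") %>%
    filter(.data$unit_length >= 2L, .data$unit_length <= 5L)
  if (pure_only) x <- filter(x, .data$purity == 1)
  x <- x %>%
    filter(lengths(.data$deltas) > 0L) %>%
    tidyr::unnest_longer(col = "deltas", values_to = "delta")
  if (nrow(x) == 0L) {
    return(tibble(unit_length = integer(), length_bin = integer(),
                  n_variant_alleles = integer(), n_in_phase = integer(),
                  percent_in_phase = double()))
  }
  x %>%
    mutate(length_bin = (.data$modal_allele %/% bin_width) * bin_width,
           in_phase = .data$delta %% .data$unit_length == 0L) %>%
    group_by(.data$unit_length, .data$length_bin) %>%
    summarise(n_variant_alleles = n(), n_in_phase = sum(.data$in_phase),
              percent_in_phase = 100 * mean(.data$in_phase),
              .groups = "drop")
}

#' Histogram of allele deltas in repeat units
#'
#' Per unit size, the frequency distribution of (allele - modal allele) /
#' unit length over non-modal alleles; whole-unit (stepwise) variation
#' puts all mass on integer positions, and e.g. 2-base events in
#' tetranucleotides appear at half-integer positions. Loci are filtered to
#' at least `min_purity` purity and a unit-size-specific minimum reference
#' length before tabulation.
#'
#' @param spectra spectra tibble.
#' @param catalog catalog tibble.
#' @param min_purity minimum locus purity.
#' @param min_length_by_unit named minimum reference tract lengths.
#' @return tibble: `unit_length`, `delta_units`, `n`, `freq` (per-unit
#'   frequencies summing to 1).
#' @export
unit_delta_histogram <- function(spectra, catalog, min_purity = 0.90,
                                 min_length_by_unit = c(`2` = 13L, `3` = 20L,
                                                        `4` = 23L, `5` = 27L)) {
  x <- spectra %>%
    left_join(select(catalog,
                     all_of(c("locus_id", "unit_length", "purity",
                              "ref_length"))),
              by = "locus_id") %>%
    filter(.data$unit_length %in% as.integer(names(min_length_by_unit)),
           .data$purity >= min_purity,
           .data$ref_length >=
             min_length_by_unit[as.character(.data$unit_length)]) %>%
    filter(lengths(.data$deltas) > 0L)
  if (nrow(x) == 0L) {
    return(tibble(unit_length = integer(), delta_units = double(),
                  n = integer(), freq = double()))
  }
  x %>%
    tidyr::unnest_longer(col = "deltas", values_to = "delta") %>%
    mutate(delta_units = .data$delta / .data$unit_length) %>%
    count(.data$unit_length, .data$delta_units) %>%
    group_by(.data$unit_length) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Length at which in-phase variation plateaus
#'
#' Operationalises "approaches a plateau": per unit size, the asymptote is
#' the mean percent-in-phase over the top length quartile, and the plateau
#' length is the smallest length bin whose value first reaches `criterion`
#' of that asymptote.
#'
#' @param phase tibble from [in_phase_analysis()].
#' @param criterion fraction of the asymptote that must be reached.
#' @param min_variants minimum variant alleles for a bin to participate.
#' @return tibble: `unit_length`, `plateau_length`, `asymptote`.
#' @export
plateau_length <- function(phase, criterion = 0.95, min_variants = 5L) {
  phase %>%
    filter(.data$n_variant_alleles >= min_variants) %>%
    group_by(.data$unit_length) %>%
    summarise({
      lens <- .data$length_bin
      pct <- .data$percent_in_phase
      top <- lens >= stats::quantile(lens, 0.75)
      asym <- mean(pct[top])
      hit <- lens[pct >= criterion * asym]
      tibble(plateau_length = if (length(hit)) min(hit) else NA_integer_,
             asymptote = asym)
    }, .groups = "drop")
}
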