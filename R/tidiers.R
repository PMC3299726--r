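#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a read-length bias bootstrap result
#'
#' One row per (group, delta bin): the observed frequency of that
#' allele-length difference among discordant loci, with the bootstrap
#' percentile band.
#'
#' @param x an `msat_bias_test` from [bootstrap_bias_test()].
#' @param ... ignored.
#' @return a tibble with `group`, `delta`, `freq`, `lo`, `hi`.
#' @export
tidy.msat_bias_test <- function(x, ...) {
  x$bands
}

#' One-row summary of a bias bootstrap
#'
#' Reports the number of discordant loci, trials, and each group's mean
#' allele-length difference (a negative mean in the shorter-read group is
#' the shorter-allele bias signature).
#'
#' @inheritParams tidy.msat_bias_test
#' @export
glance.msat_bias_test <- function(x, ...) {
  means <- x$bands %>%
    group_by(.data$group) %>%
    summarise(m = sum(.data$delta * .data$freq), .groups = "drop")
  tibble(n_discordant = x$n_discordant, n_trials = x$n_trials,
         seed = x$seed,
         mean_delta_a = means$m[means$group == "a"],
         mean_delta_b = means$m[means$group == "b"])
}
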