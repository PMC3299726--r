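BASES <- c("A", "C", "G", "T")

#' Canonical rotation of a repeat unit
#'
#' Returns the lexicographically minimal rotation of each unit string, so
#' that e.g. "CA", "AC" and any phase of the same motif share one label.
#' Reverse complements are not merged: calls are made on the reference
#' strand.
#'
#' @param unit character vector of nucleotide motifs.
#' @return character vector of canonical rotations.
#' @export
#' @examples
#' canonical_rotation(c("CA", "GAT", "A"))
canonical_rotation <- function(unit) {
  vapply(toupper(unit), function(u) {
    n <- nchar(u)
    if (n <= 1L) return(u)
    rots <- vapply(seq_len(n), function(i) {
      paste0(substr(u, i, n), substr(u, 1L, i - 1L))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# modal u-mer of a tract read in frame from its first base
modal_unit <- function(tract, u) {
  n <- nchar(tract)
  if (n < u) return(substr(tract, 1L, n))
  starts <- seq(1L, n - u + 1L, by = u)
  words <- substring(tract, starts, starts + u - 1L)
  tab <- sort(table(words), decreasing = TRUE)
  names(tab)[1L]
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# count matching offset-u self-comparisons in a tract (purity numerator)
count_unit_matches <- function(tract, u) {
  n <- nchar(tract)
  if (n <= u) return(0L)
  s <- strsplit(tract, "")[[1]]
  sum(s[(u + 1L):n] == s[1:(n - u)])
}

# coerce a reference (named character vector, list, or DNAStringSet) to a
# named character vector of chromosome sequences
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.list(reference)) {
    out <- vapply(reference, as.character, character(1))
  } else {
    out <- reference
  }
  if (is.null(names(out)) || anyNA(names(out))) {
    stop("reference sequences must be named by chromosome", call. = FALSE)
  }
  toupper(out)
}

#' Read a reference genome from FASTA
#'
#' @param path path to a (plain-text) FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_reference(x)
}
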