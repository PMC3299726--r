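# Exhaustive brute-force scorer, independent of the package's detector.
# For one unit size, scores every comparison interval [a, b] (comparison i
# tests s[i] == s[i - u], 1-based) as 2*matches - 5*mismatches + 2u and
# returns all intervals at or above min_score as 0-based tracts.
oracle_intervals <- function(seq, u, min_score = 14L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n <= u) {
    return(data.frame(start = integer(), end = integer(), score = integer()))
  }
  ok <- s %in% c("A", "C", "G", "T")
  m <- s[(u + 1):n] == s[1:(n - u)] & ok[(u + 1):n] & ok[1:(n - u)]
  v <- ifelse(m, 2L, -5L)
  P <- c(0L, cumsum(v)) # P[k+1] = sum of first k comparison values
  nc <- length(v)
  sc <- outer(P[-1], P[-(nc + 1)], "-") # sc[b, a] = sum over a..b
  hit <- which(sc + 2L * u >= min_score & row(sc) >= col(sc), arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(start = integer(), end = integer(), score = integer()))
  }
  a <- hit[, 2]; b <- hit[, 1] # comparison indices
  data.frame(start = a - 1L, # tract start 0-based: comparison a covers s[a+u]
             end = b + u, # exclusive end
             score = sc[hit] + 2L * u)
}

# direct recomputation of matches for a reported tract
oracle_matches <- function(seq, start0, end0, u) {
  tract <- substr(seq, start0 + 1L, end0)
  s <- strsplit(tract, "")[[1]]
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  sum(s[(u + 1):n] == s[1:(n - u)] & ok[(u + 1):n] & ok[1:(n - u)])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_unit_helper <- function(u) microsat:::random_unit(u)

# plant a perfect repeat inside random flanks with guard bases that stop
# boundary extension at every unit size that divides into the tract period
plant_repeat <- function(unit, len, flank = 60L) {
  u <- nchar(unit)
  tract <- substr(strrep(unit, ceiling(len / u) + 1L), 1L, len)
  tr <- strsplit(tract, "")[[1]]
  dangerous <- seq(u, 5L, by = u)
  left <- right <- character(3L)
  for (k in 1:3) {
    banned_l <- banned_r <- character(0)
    for (du in dangerous) {
      off <- du - k
      banned_l <- c(banned_l, if (off >= 0) tr[off + 1L] else left[-off])
      banned_r <- c(banned_r, if (off >= 0) tr[len - off] else right[-off])
    }
    left[k] <- sample(setdiff(c("A", "C", "G", "T"), banned_l), 1L)
    right[k] <- sample(setdiff(c("A", "C", "G", "T"), banned_r), 1L)
  }
  fl <- random_seq(flank)
  list(seq = paste0(fl, paste(rev(left), collapse = ""), tract,
                    paste(right, collapse = ""), random_seq(flank)),
       start = flank + 3L, end = flank + 3L + len)
}
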