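# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they validate.

# Complex concentration by bisection on the mass-action root
# kas * (p0 - x) * (L0 - x) - x = 0 over x in [0, min(p0, L0)].
bisect_complex <- function(kas, p0, L0, iter = 200) {
  f <- function(x) kas * (p0 - x) * (L0 - x) - x
  lo <- 0
  hi <- min(p0, L0)
  if (hi == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorized bisection over parallel grids (same root as above).
bisect_complex_vec <- function(kas, p0, L0, iter = 80) {
  lo <- rep(0, length(L0))
  hi <- pmin(p0, L0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    pos <- kas * (p0 - mid) * (L0 - mid) - mid > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

# Exhaustive per-column enumeration of family-discriminating positions,
# written independently of find_discriminating_positions().
brute_discriminating_columns <- function(aln, threshold, gap_policy = "strict") {
  fams <- sort(unique(aln$families))
  hits <- integer(0)
  for (j in seq_len(ncol(aln$mat))) {
    cons <- list()
    ok <- TRUE
    for (f in fams) {
      col <- aln$mat[aln$families == f, j]
      if (gap_policy == "strict") {
        if (any(col == "-")) { ok <- FALSE; break }
      } else {
        col <- col[col != "-"]
        if (length(col) == 0) { ok <- FALSE; break }
      }
      counts <- table(col)
      best <- which.max(counts)
      if (counts[best] / length(col) + 1e-12 < threshold) { ok <- FALSE; break }
      cons[[f]] <- names(counts)[best]
    }
    if (ok && cons[[fams[1]]] != cons[[fams[2]]]) hits <- c(hits, j)
  }
  hits
}

# Standard simulated truth used across fit tests (affinity varies per test).
test_truth <- function(kas) binding_parameters(kas, 0.1, 1000, 5000, 1.5)
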