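# Independent alignment oracles.
#
# oracle_local_score: plain-R affine-gap local DP written from the
# recurrence (matrix form, no traceback) -- independent of the compiled
# implementation.
#
# enumerate_local_score: true exhaustive enumeration -- every substring pair
# and, for each, every monotone alignment path (recursion over edit
# operations carrying the affine gap state). Exponential; tiny strings only.
# It grounds the R DP, which in turn checks the compiled aligner at scale.

oracle_local_score <- function(q, s, match = 2, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  n <- nchar(q); m <- nchar(s)
  if (n == 0 || m == 0) return(0)
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-1e9, n + 1, m + 1)
  F <- matrix(-1e9, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] + gap_open, E[i - 1, j]) + gap_extend
      F[i, j] <- max(H[i, j - 1] + gap_open, F[i, j - 1]) + gap_extend
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match else
        mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

enumerate_global_score <- function(qc, sc, state, match, mismatch,
                                   gap_open, gap_extend) {
  if (!length(qc) && !length(sc)) return(0)
  opts <- -Inf
  if (length(qc) && length(sc)) {
    sub <- if (qc[1] == sc[1] && qc[1] != "N") match else mismatch
    opts <- max(opts, sub + enumerate_global_score(qc[-1], sc[-1], "M",
                                                   match, mismatch,
                                                   gap_open, gap_extend))
  }
  if (length(qc)) {
    cost <- if (identical(state, "I")) gap_extend else gap_open + gap_extend
    opts <- max(opts, cost + enumerate_global_score(qc[-1], sc, "I",
                                                    match, mismatch,
                                                    gap_open, gap_extend))
  }
  if (length(sc)) {
    cost <- if (identical(state, "D")) gap_extend else gap_open + gap_extend
    opts <- max(opts, cost + enumerate_global_score(qc, sc[-1], "D",
                                                    match, mismatch,
                                                    gap_open, gap_extend))
  }
  opts
}

enumerate_local_score <- function(q, s, match = 2, mismatch = -2,
                                  gap_open = -5, gap_extend = -2) {
  qc_full <- strsplit(q, "")[[1]]; sc_full <- strsplit(s, "")[[1]]
  n <- length(qc_full); m <- length(sc_full)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, enumerate_global_score(
        qc_full[i1:i2], sc_full[j1:j2], "none", match, mismatch,
        gap_open, gap_extend))
    }
  }
  best
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
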