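#' Alignment scoring scheme
#'
#' Affine-gap scoring used by the internal aligner. A gap of length L costs
#' `gap_open + L * gap_extend`, so a single-base gap costs
#' `gap_open + gap_extend` (default -7). `N` bases never match (scored as a
#' mismatch, even against `N`).
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open gap opening penalty (< 0), charged once per gap.
#' @param gap_extend per-base gap extension penalty (< 0).
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -2L,
                           gap_open = -5L, gap_extend = -2L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

new_alignment <- function(raw) {
  identity <- if (raw$n_aligned_cols > 0) raw$n_match / raw$n_aligned_cols else 0
  structure(list(score = raw$score,
                 query_start = raw$query_start, query_end = raw$query_end,
                 subject_start = raw$subject_start,
                 subject_end = raw$subject_end,
                 cigar = raw$cigar, identity = identity,
                 n_match = raw$n_match,
                 n_aligned_cols = raw$n_aligned_cols),
            class = "ig_alignment")
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman local alignment of two nucleotide strings under
#' [scoring_scheme()]. Coordinates are 1-based inclusive. When no
#' positive-scoring alignment exists (e.g. an empty sequence) the score is 0
#' and the alignment empty. The best-scoring cell is selected scanning query
#' then subject positions in ascending order, so ties resolve to the
#' earliest endpoint; traceback prefers diagonal steps, making the result
#' deterministic.
#'
#' @param query,subject nucleotide strings over `{A,C,G,T,N}`.
#' @param scheme a [scoring_scheme()].
#' @return an `ig_alignment`: score, query/subject start and end, CIGAR
#'   (`M` = aligned column, `I` = query-only base, `D` = subject-only base),
#'   identity (matches / aligned columns, gaps excluded).
#' @export
align_local <- function(query, subject, scheme = scoring_scheme()) {
  raw <- .sw_align_cpp(toupper(query), toupper(subject), scheme$match,
                       scheme$mismatch, scheme$gap_open, scheme$gap_extend)
  new_alignment(raw)
}

#' Global alignment with affine gaps
#'
#' Needleman-Wunsch alignment of two full-length strings (end gaps are
#' penalized); used internally by the center-star consensus step.
#'
#' @inheritParams align_local
#' @return list with `score` and `cigar`.
#' @export
align_global <- function(query, subject, scheme = scoring_scheme()) {
  .nw_align_cpp(toupper(query), toupper(subject), scheme$match,
                scheme$mismatch, scheme$gap_open, scheme$gap_extend)
}

#' @export
print.ig_alignment <- function(x, ...) {
  cat(sprintf("ig_alignment score=%d q=%d..%d s=%d..%d id=%.3f %s\n",
              x$score, x$query_start, x$query_end, x$subject_start,
              x$subject_end, x$identity, x$cigar))
  invisible(x)
}

cigar_ops <- function(cigar) {
  if (!nzchar(cigar)) {
    return(data.frame(len = integer(), op = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1L]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# Expand an alignment into per-column (query_pos, subject_pos) pairs;
# NA marks the gapped side. Positions are 1-based on the full sequences.
alignment_columns <- function(aln) {
  ops <- cigar_ops(aln$cigar)
  if (!nrow(ops)) {
    return(data.frame(query_pos = integer(), subject_pos = integer()))
  }
  q <- aln$query_start
  s <- aln$subject_start
  qs <- integer(0); ss <- integer(0)
  for (k in seq_len(nrow(ops))) {
    n <- ops$len[k]
    if (ops$op[k] == "M") {
      qs <- c(qs, q:(q + n - 1L)); ss <- c(ss, s:(s + n - 1L))
      q <- q + n; s <- s + n
    } else if (ops$op[k] == "I") {
      qs <- c(qs, q:(q + n - 1L)); ss <- c(ss, rep(NA_integer_, n))
      q <- q + n
    } else {
      qs <- c(qs, rep(NA_integer_, n)); ss <- c(ss, s:(s + n - 1L))
      s <- s + n
    }
  }
  data.frame(query_pos = qs, subject_pos = ss)
}

# Ungapped extension of a local alignment toward both sequence ends: columns
# are appended 1:1 while both sequences have bases left, regardless of
# match/mismatch. Appropriate for amplicons expected to cover the full
# germline segment, where local alignment would otherwise clip terminal
# mismatches (e.g. hypermutation at the first or last germline base).
extend_alignment_ends <- function(aln, query, subject) {
  if (aln$n_aligned_cols == 0) return(aln)
  ext5 <- min(aln$query_start - 1L, aln$subject_start - 1L)
  ext3 <- min(nchar(query) - aln$query_end, nchar(subject) - aln$subject_end)
  if (ext5 == 0L && ext3 == 0L) return(aln)
  qs <- aln$query_start - ext5
  ss <- aln$subject_start - ext5
  qe <- aln$query_end + ext3
  se <- aln$subject_end + ext3
  ops <- cigar_ops(aln$cigar)
  if (ext5 > 0L) {
    if (nrow(ops) && ops$op[1L] == "M") ops$len[1L] <- ops$len[1L] + ext5
    else ops <- rbind(data.frame(len = ext5, op = "M"), ops)
  }
  if (ext3 > 0L) {
    if (nrow(ops) && ops$op[nrow(ops)] == "M") {
      ops$len[nrow(ops)] <- ops$len[nrow(ops)] + ext3
    } else ops <- rbind(ops, data.frame(len = ext3, op = "M"))
  }
  cigar <- paste0(ops$len, ops$op, collapse = "")
  qchars <- strsplit(substr(query, qs, qe), "")[[1L]]
  schars <- strsplit(substr(subject, ss, se), "")[[1L]]
  cols <- alignment_columns(list(cigar = cigar, query_start = qs,
                                 subject_start = ss))
  mcols <- !is.na(cols$query_pos) & !is.na(cols$subject_pos)
  qb <- qchars[cols$query_pos[mcols] - qs + 1L]
  sb <- schars[cols$subject_pos[mcols] - ss + 1L]
  n_match <- sum(qb == sb & qb != "N")
  structure(list(score = aln$score, query_start = qs, query_end = qe,
                 subject_start = ss, subject_end = se, cigar = cigar,
                 identity = if (sum(mcols)) n_match / sum(mcols) else 0,
                 n_match = n_match, n_aligned_cols = sum(mcols)),
            class = "ig_alignment")
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
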