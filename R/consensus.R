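#' Group reads of one cell and locus by V-J combination
#'
#' Reads from one event and locus are grouped by their gene-level (V, J)
#' combination and ranked by read support; the most frequent combination
#' becomes rank 1, the second rank 2. Ties resolve by summed V-alignment
#' score, then lexicographically smaller (V, J) key. Groups beyond rank 2
#' are discarded but counted, as are reads lacking a V or J assignment.
#'
#' @param read_tbl data.frame with one row per read: `read_id`, `v_gene`,
#'   `j_gene` (NA when unassigned), `v_score`.
#' @return data.frame of at most two rows (`v_gene`, `j_gene`, `support`,
#'   `sum_v_score`, `rank`), with attributes `n_excluded` (reads without
#'   V or J), `n_discarded_groups` and `read_ids` (list column-less list of
#'   read id vectors, one per rank).
#' @export
group_reads <- function(read_tbl) {
  eligible <- !is.na(read_tbl$v_gene) & !is.na(read_tbl$j_gene)
  n_excluded <- sum(!eligible)
  tbl <- read_tbl[eligible, , drop = FALSE]
  if (!nrow(tbl)) {
    out <- data.frame(v_gene = character(), j_gene = character(),
                      support = integer(), sum_v_score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- n_excluded
    attr(out, "n_discarded_groups") <- 0L
    attr(out, "read_ids") <- list()
    return(out)
  }
  key <- paste(tbl$v_gene, tbl$j_gene, sep = "\r")
  agg <- aggregate(list(support = rep(1L, nrow(tbl)),
                        sum_v_score = tbl$v_score),
                   by = list(key = key), FUN = sum)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  agg$v_gene <- vapply(parts, `[[`, "", 1L)
  agg$j_gene <- vapply(parts, `[[`, "", 2L)
  ord <- order(-agg$support, -agg$sum_v_score,
               paste(agg$v_gene, agg$j_gene))
  agg <- agg[ord, ]
  n_groups <- nrow(agg)
  keep <- head(agg, 2L)
  keep$rank <- seq_len(nrow(keep))
  out <- keep[, c("v_gene", "j_gene", "support", "sum_v_score", "rank")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_discarded_groups") <- max(0L, n_groups - 2L)
  attr(out, "read_ids") <- lapply(seq_len(nrow(out)), function(r) {
    tbl$read_id[key == paste(out$v_gene[r], out$j_gene[r], sep = "\r")]
  })
  out
}

#' Build a per-cell consensus from a read group
#'
#' A single read is returned verbatim (source `single_read`). For two or
#' more reads a center-star multiple alignment is built: the read with the
#' highest V-alignment score (ties: lexicographically smallest read id) is
#' the center; every other read is globally aligned to it and gaps are
#' projected into a common column space. Each column is resolved by majority
#' vote over non-gap bases, ties going to the center read's base;
#' gap-majority columns are omitted. The mean per-column agreement (fraction
#' of non-gap bases matching the consensus base) is recorded. Groups larger
#' than `max_reads` are subsampled deterministically.
#'
#' @param sequences named character vector of read sequences (names = read
#'   ids), tags already trimmed.
#' @param v_scores numeric vector parallel to `sequences` (V alignment score
#'   per read); defaults to read length.
#' @param scheme a [scoring_scheme()].
#' @param max_reads cap on reads entering the MSA.
#' @param subsample_seed seed for the subsampling draw.
#' @return a `consensus_record` list: `sequence`, `n_reads`,
#'   `column_agreement`, `source` (`consensus` or `single_read`), `capped`.
#' @export
build_consensus <- function(sequences, v_scores = NULL,
                            scheme = scoring_scheme(), max_reads = 500L,
                            subsample_seed = 1L) {
  stopifnot(length(sequences) >= 1L)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("read%04d", seq_along(sequences))
  }
  if (is.null(v_scores)) v_scores <- nchar(sequences)
  n_total <- length(sequences)
  capped <- FALSE
  if (n_total > max_reads) {
    old <- .Random.seed_save()
    set.seed(subsample_seed)
    keep <- sort(sample.int(n_total, max_reads))
    .Random.seed_restore(old)
    sequences <- sequences[keep]
    v_scores <- v_scores[keep]
    capped <- TRUE
  }
  if (length(sequences) == 1L) {
    return(structure(list(sequence = unname(sequences[[1L]]),
                          n_reads = 1L, column_agreement = 1,
                          source = "single_read", capped = capped),
                     class = "consensus_record"))
  }
  ord <- order(-v_scores, names(sequences))
  center_id <- names(sequences)[ord[1L]]
  center <- toupper(sequences[[center_id]])
  others <- setdiff(names(sequences), center_id)
  L <- nchar(center)
  n <- length(sequences)
  # base matrix over center columns; insertions keyed by (center_pos, k)
  base_mat <- matrix("-", nrow = n, ncol = L,
                     dimnames = list(c(center_id, others), NULL))
  base_mat[1L, ] <- strsplit(center, "")[[1L]]
  ins <- new.env(parent = emptyenv())
  for (rid in others) {
    q <- toupper(sequences[[rid]])
    aln <- align_global(q, center, scheme)
    ops <- cigar_ops(aln$cigar)
    qchars <- strsplit(q, "")[[1L]]
    qi <- 0L; ci <- 0L
    for (k in seq_len(nrow(ops))) {
      m <- ops$len[k]
      if (ops$op[k] == "M") {
        base_mat[rid, (ci + 1L):(ci + m)] <- qchars[(qi + 1L):(qi + m)]
        qi <- qi + m; ci <- ci + m
      } else if (ops$op[k] == "D") {
        ci <- ci + m
      } else { # insertion relative to center, anchored after center col ci
        for (t in seq_len(m)) {
          keyname <- sprintf("%06d.%03d", ci, t)
          col <- if (exists(keyname, envir = ins)) get(keyname, envir = ins)
                 else setNames(rep("-", n), rownames(base_mat))
          col[rid] <- qchars[qi + t]
          assign(keyname, col, envir = ins)
        }
        qi <- qi + m
      }
    }
  }
  # assemble ordered columns: insertions after their anchor center column
  col_list <- list()
  ins_keys <- sort(ls(ins))
  ins_anchor <- as.integer(sub("\\..*$", "", ins_keys))
  add_ins <- function(anchor) {
    for (keyname in ins_keys[ins_anchor == anchor]) {
      col_list[[length(col_list) + 1L]] <<-
        list(bases = get(keyname, envir = ins), center_base = "-")
    }
  }
  add_ins(0L)
  for (p in seq_len(L)) {
    col_list[[length(col_list) + 1L]] <- list(bases = base_mat[, p],
                                              center_base = base_mat[1L, p])
    add_ins(p)
  }
  cons <- character(0)
  agreements <- numeric(0)
  for (col in col_list) {
    bases <- col$bases
    nongap <- bases[bases != "-"]
    if (length(nongap) <= length(bases) - length(nongap)) next # gap majority
    tab <- table(nongap)
    top <- names(tab)[tab == max(tab)]
    pick <- if (length(top) == 1L) top
            else if (col$center_base %in% top) col$center_base
            else sort(top)[1L]
    cons <- c(cons, pick)
    agreements <- c(agreements, sum(nongap == pick) / length(nongap))
  }
  structure(list(sequence = paste(cons, collapse = ""),
                 n_reads = length(sequences),
                 column_agreement = if (length(agreements)) mean(agreements)
                                    else 0,
                 source = "consensus", capped = capped),
            class = "consensus_record")
}

#' Build the secondary consensus when a second V-J group is supported
#'
#' Emitted iff a rank-2 group exists, has support of at least
#' `min_secondary_support` and a (V, J) key different from rank 1; it flags
#' wells where two distinct transcripts (e.g. a sorting doublet) were
#' present.
#'
#' @param groups output of [group_reads()].
#' @param sequences named character vector covering at least the rank-2
#'   group's read ids.
#' @param v_scores named numeric vector of per-read V scores.
#' @param min_secondary_support minimum rank-2 read support.
#' @param scheme a [scoring_scheme()].
#' @param max_reads,subsample_seed see [build_consensus()].
#' @return a `consensus_record` or `NULL`.
#' @export
build_secondary <- function(groups, sequences, v_scores = NULL,
                            min_secondary_support = 2L,
                            scheme = scoring_scheme(), max_reads = 500L,
                            subsample_seed = 1L) {
  if (nrow(groups) < 2L) return(NULL)
  g2 <- groups[groups$rank == 2L, ]
  if (g2$support < min_secondary_support) return(NULL)
  if (identical(c(g2$v_gene, g2$j_gene),
                c(groups$v_gene[groups$rank == 1L],
                  groups$j_gene[groups$rank == 1L]))) {
    return(NULL)
  }
  ids <- attr(groups, "read_ids")[[2L]]
  build_consensus(sequences[ids],
                  if (is.null(v_scores)) NULL else v_scores[ids],
                  scheme, max_reads, subsample_seed)
}
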