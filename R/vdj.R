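#' Default minimum segment alignment scores
#'
#' Under the default scoring (+2 match) a V hit needs roughly a 35 nt exact
#' match to pass the V threshold of 60; J/D/C thresholds scale with typical
#' segment lengths.
#'
#' @export
default_min_scores <- function() {
  c(V = 60L, J = 20L, D = 10L, C = 30L)
}

best_hit <- function(query, candidates, scheme, q_offset = 0L,
                     extend = FALSE) {
  if (!nrow(candidates) || !nzchar(query)) return(NULL)
  query <- toupper(query)
  # score-only pass ranks candidates; full traceback only for the winner(s)
  scores <- .sw_score_multi_cpp(query, candidates$sequence, scheme$match,
                                scheme$mismatch, scheme$gap_open,
                                scheme$gap_extend)
  if (max(scores) <= 0) return(NULL)
  top <- which(scores == max(scores))
  alns <- lapply(top, function(i) align_local(query, candidates$sequence[i],
                                              scheme))
  idents <- vapply(alns, `[[`, 0, "identity")
  ord <- order(-idents, candidates$segment_id[top])
  k <- top[ord[1L]]
  aln <- alns[[ord[1L]]]
  if (extend) aln <- extend_alignment_ends(aln, query, candidates$sequence[k])
  if (q_offset > 0L) {
    aln$query_start <- aln$query_start + q_offset
    aln$query_end <- aln$query_end + q_offset
  }
  list(segment_id = candidates$segment_id[k], alignment = aln,
       tied_ids = candidates$segment_id[scores == max(scores)])
}

#' Assign germline V, D, J and constant segments to a sequence
#'
#' The best-scoring V across all loci fixes the locus. J is then searched in
#' the query right of the V alignment end minus 4 nt (alignments of adjacent
#' segments may overlap by at most 4 nt); the D segment (IGH only) is
#' searched strictly between the V end and the J start and requires an
#' aligned length of at least 5 nt; the constant region is searched right of
#' J. Hits below `min_scores` are absent. Score ties resolve by higher
#' identity, then lexicographically smaller segment id. V and J alignments
#' are extended ungapped to the germline segment ends (see the package
#' vignette) unless `extend_ends = FALSE`.
#'
#' @param seq nucleotide string (a read or consensus, tags trimmed).
#' @param ref a [germline_reference()].
#' @param scheme a [scoring_scheme()].
#' @param min_scores named integer vector with elements V, D, J, C.
#' @param extend_ends extend V/J alignments to full germline coverage.
#' @return a `segment_assignment`: list with `v`, `d`, `j`, `c` (each `NULL`
#'   or `list(segment_id, alignment)`), `locus`, and `unannotatable`.
#' @export
assign_segments <- function(seq, ref, scheme = scoring_scheme(),
                            min_scores = default_min_scores(),
                            extend_ends = TRUE) {
  seq <- toupper(seq)
  segs <- ref$segments
  empty <- structure(list(v = NULL, d = NULL, j = NULL, c = NULL,
                          locus = NA_character_, unannotatable = TRUE),
                     class = "segment_assignment")
  v_hit <- best_hit(seq, segs[segs$segment_type == "V", ], scheme,
                    extend = extend_ends)
  if (is.null(v_hit) || v_hit$alignment$score < min_scores[["V"]]) {
    return(empty)
  }
  locus <- segs$locus[segs$segment_id == v_hit$segment_id]
  v_end <- v_hit$alignment$query_end

  j_from <- max(1L, v_end - 3L)
  j_window <- substr(seq, j_from, nchar(seq))
  j_hit <- best_hit(j_window,
                    segs[segs$segment_type == "J" & segs$locus == locus, ],
                    scheme, q_offset = j_from - 1L, extend = extend_ends)
  if (!is.null(j_hit) && j_hit$alignment$score < min_scores[["J"]]) {
    j_hit <- NULL
  }

  d_hit <- NULL
  if (locus == "IGH" && !is.null(j_hit)) {
    d_from <- v_end + 1L
    d_to <- j_hit$alignment$query_start - 1L
    if (d_to - d_from + 1L >= 5L) {
      d_window <- substr(seq, d_from, d_to)
      d_hit <- best_hit(d_window, segs[segs$segment_type == "D", ], scheme,
                        q_offset = d_from - 1L)
      if (!is.null(d_hit) &&
          (d_hit$alignment$score < min_scores[["D"]] ||
           d_hit$alignment$n_aligned_cols < 5L)) {
        d_hit <- NULL
      }
    }
  }

  c_hit <- NULL
  if (!is.null(j_hit)) {
    c_from <- max(1L, j_hit$alignment$query_end - 3L)
    if (c_from <= nchar(seq)) {
      c_window <- substr(seq, c_from, nchar(seq))
      c_hit <- best_hit(c_window,
                        segs[segs$segment_type == "C" & segs$locus == locus, ],
                        scheme, q_offset = c_from - 1L)
      if (!is.null(c_hit) && c_hit$alignment$score < min_scores[["C"]]) {
        c_hit <- NULL
      }
    }
  }
  structure(list(
    v = v_hit[c("segment_id", "alignment")],
    d = if (is.null(d_hit)) NULL else d_hit[c("segment_id", "alignment")],
    j = if (is.null(j_hit)) NULL else j_hit[c("segment_id", "alignment")],
    c = if (is.null(c_hit)) NULL else c_hit[c("segment_id", "alignment")],
    locus = locus, unannotatable = FALSE
  ), class = "segment_assignment")
}

# germline -> query position map from alignment columns (both non-gap)
germline_to_query_map <- function(aln) {
  cols <- alignment_columns(aln)
  cols <- cols[!is.na(cols$subject_pos), , drop = FALSE]
  map <- rep(NA_integer_, max(cols$subject_pos, 0L))
  ok <- !is.na(cols$query_pos)
  map[cols$subject_pos[ok]] <- cols$query_pos[ok]
  map
}

#' Project FR/CDR regions and locate the junction on the query
#'
#' The V segment's germline region map (FR1..FR3, CDR1..CDR2) is projected
#' through the V alignment onto query coordinates; insertions and deletions
#' shift downstream boundaries accordingly, and regions are truncated to the
#' aligned extent. The junction starts right after the projected FR3 end and
#' runs through the start of the J alignment plus the J segment's conserved
#' first codon (3 nt). If the V alignment does not reach the end of FR3 the
#' junction is undefined and the flag `truncated_v` is raised.
#'
#' @param seq query nucleotide string.
#' @param assignment a [assign_segments()] result with V present.
#' @param ref the [germline_reference()].
#' @return list with `regions` (data.frame region/start/end in query
#'   coordinates), `junction` (length-2 integer vector or `NULL`) and
#'   `flags` (character).
#' @export
annotate_regions <- function(seq, assignment, ref) {
  if (is.null(assignment$v)) stop("V assignment required")
  v_aln <- assignment$v$alignment
  rmap <- region_map_for(ref, assignment$v$segment_id)
  g2q <- germline_to_query_map(v_aln)
  flags <- character(0)
  regions <- list()
  for (k in seq_len(nrow(rmap))) {
    gs <- max(rmap$start[k], v_aln$subject_start)
    ge <- min(rmap$end[k], v_aln$subject_end)
    if (gs > ge) next
    qpos <- g2q[gs:ge]
    qpos <- qpos[!is.na(qpos)]
    if (!length(qpos)) next
    regions[[length(regions) + 1L]] <- data.frame(
      region = rmap$region[k], start = min(qpos), end = max(qpos),
      stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(region = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  junction <- NULL
  fr3_end <- rmap$end[rmap$region == "FR3"]
  if (!length(fr3_end) || v_aln$subject_end < fr3_end) {
    flags <- c(flags, "truncated_v")
  } else if (!is.null(assignment$j)) {
    q_fr3_end <- g2q[fr3_end]
    if (!is.na(q_fr3_end)) {
      j_start <- assignment$j$alignment$query_start
      j_end3 <- min(j_start + 2L, nchar(seq))
      if (q_fr3_end + 1L <= j_end3) {
        junction <- c(start = q_fr3_end + 1L, end = j_end3)
      }
    }
  }
  list(regions = regions, junction = junction, flags = flags)
}

region_label_for_pos <- function(rmap, pos) {
  hit <- rmap$region[rmap$start <= pos & rmap$end >= pos]
  if (length(hit)) hit[1L] else NA_character_
}

mutations_from_alignment <- function(seq, aln, segment_id, germline_seq,
                                     rmap = NULL) {
  cols <- alignment_columns(aln)
  if (!nrow(cols)) {
    return(empty_mutations())
  }
  qchars <- strsplit(seq, "")[[1L]]
  gchars <- strsplit(germline_seq, "")[[1L]]
  qp <- cols$query_pos
  gp <- cols$subject_pos
  qb <- ifelse(is.na(qp), "-", qchars[ifelse(is.na(qp), 1L, qp)])
  gb <- ifelse(is.na(gp), "-", gchars[ifelse(is.na(gp), 1L, gp)])
  # insertion anchor: last germline position seen before the column
  gp_fill <- gp
  seen <- !is.na(gp_fill)
  gp_fill <- c(aln$subject_start - 1L, gp_fill[seen])[cumsum(seen) + 1L]
  is_sub <- !is.na(qp) & !is.na(gp) & qb != gb & qb != "N"
  is_ins <- is.na(gp) & qb != "N"
  is_del <- is.na(qp)
  keep <- is_sub | is_ins | is_del
  if (!any(keep)) return(empty_mutations())
  df <- data.frame(
    segment_id = segment_id,
    germline_pos = ifelse(is.na(gp), gp_fill, gp)[keep],
    germline_base = gb[keep],
    query_base = qb[keep],
    kind = ifelse(is_sub, "substitution",
                  ifelse(is_del, "deletion", "insertion"))[keep],
    stringsAsFactors = FALSE
  )
  df$region <- if (!is.null(rmap) && nrow(rmap)) {
    vapply(df$germline_pos, function(p) region_label_for_pos(rmap, p), "")
  } else NA_character_
  df
}

empty_mutations <- function() {
  data.frame(segment_id = character(), germline_pos = integer(),
             germline_base = character(), query_base = character(),
             kind = character(), region = character(),
             stringsAsFactors = FALSE)
}

#' Call somatic hypermutations against the germline
#'
#' Walks the aligned columns of the V alignment (and the J alignment when
#' present): a mismatch column yields a substitution at the germline
#' position, a germline gap an insertion anchored to the preceding germline
#' position, a query gap a deletion. Columns in the junction / N region lie
#' outside the V and J alignments and are never counted; `N` query bases
#' never produce calls. V mutations are labelled with their FR/CDR region
#' where the region map covers the position.
#'
#' @inheritParams annotate_regions
#' @return data.frame: `segment_id`, `germline_pos`, `germline_base`,
#'   `query_base`, `kind`, `region`.
#' @export
call_mutations <- function(seq, assignment, ref) {
  if (is.null(assignment$v)) stop("V alignment required for mutation calling")
  seq <- toupper(seq)
  v_id <- assignment$v$segment_id
  out <- mutations_from_alignment(
    seq, assignment$v$alignment, v_id,
    ref_segment(ref, v_id)$sequence, region_map_for(ref, v_id))
  if (!is.null(assignment$j)) {
    j_id <- assignment$j$segment_id
    out <- rbind(out, mutations_from_alignment(
      seq, assignment$j$alignment, j_id, ref_segment(ref, j_id)$sequence))
  }
  rownames(out) <- NULL
  out
}

#' Assign the constant-region isotype
#'
#' Realigns every constant-region segment of the assigned locus right of the
#' J alignment; the best hit is accepted iff its aligned length is at least
#' `min_c_len` and its identity at least `min_c_identity`. A score tie
#' between subclasses of one class (e.g. IGHG1 vs IGHG2) yields the generic
#' class label (`IGHG`); sequences without sufficient constant region get
#' `NA` (common for short reads, not an error).
#'
#' @inheritParams annotate_regions
#' @param min_c_len minimum aligned constant-region length (nt).
#' @param min_c_identity minimum alignment identity.
#' @param scheme a [scoring_scheme()].
#' @return isotype label (gene level, e.g. `"IGHG1"`, or class label on
#'   subclass ties) or `NA_character_`.
#' @export
assign_isotype <- function(seq, assignment, ref, min_c_len = 30L,
                           min_c_identity = 0.95,
                           scheme = scoring_scheme()) {
  if (is.null(assignment$j) || is.na(assignment$locus)) return(NA_character_)
  seq <- toupper(seq)
  c_from <- max(1L, assignment$j$alignment$query_end - 3L)
  if (c_from > nchar(seq)) return(NA_character_)
  window <- substr(seq, c_from, nchar(seq))
  cand <- ref$segments[ref$segments$segment_type == "C" &
                         ref$segments$locus == assignment$locus, ]
  if (!nrow(cand)) return(NA_character_)
  scores <- .sw_score_multi_cpp(toupper(window), cand$sequence, scheme$match,
                                scheme$mismatch, scheme$gap_open,
                                scheme$gap_extend)
  best <- max(scores)
  top <- which(scores == best)
  alns <- lapply(top, function(i) align_local(window, cand$sequence[i],
                                              scheme))
  k <- top[order(-vapply(alns, `[[`, 0, "identity"),
                 cand$segment_id[top])][1L]
  aln <- alns[[match(k, top)]]
  if (aln$n_aligned_cols < min_c_len || aln$identity < min_c_identity ||
      best <= 0) {
    return(NA_character_)
  }
  genes <- unique(ig_gene(cand$segment_id[top]))
  if (length(genes) > 1L) {
    classes <- unique(sub("[0-9]+$", "", genes))
    if (length(classes) == 1L) return(classes)
  }
  ig_gene(cand$segment_id[k])
}

.pkg_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.pkg_cache$gc)) .pkg_cache$gc <- Biostrings::GENETIC_CODE
  .pkg_cache$gc
}

translate_nt <- function(nt) {
  if (!nzchar(nt) || nchar(nt) %% 3L != 0L) return(NA_character_)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  gc <- genetic_code()
  aa <- ifelse(grepl("N", codons), "X", gc[codons])
  if (anyNA(aa)) return(NA_character_)
  paste(aa, collapse = "")
}

#' Productivity of a chain annotation
#'
#' A rearrangement is productive iff a junction is defined, its nucleotide
#' length is divisible by 3, and the reading frame fixed by the germline V
#' start contains no stop codon from the V through the end of the J
#' alignment.
#'
#' @param annotation a chain annotation as built by [annotate_chain()] (needs
#'   `seq`, `assignment` and `junction`).
#' @return list with `productive` (logical) and `reasons` (character vector,
#'   empty when productive; otherwise among `no_junction`, `out_of_frame`,
#'   `stop_codon`).
#' @export
classify_productive <- function(annotation) {
  reasons <- character(0)
  junction <- annotation$junction
  if (is.null(junction)) {
    return(list(productive = FALSE, reasons = "no_junction"))
  }
  jlen <- junction[["end"]] - junction[["start"]] + 1L
  if (jlen %% 3L != 0L) reasons <- c(reasons, "out_of_frame")
  v_aln <- annotation$assignment$v$alignment
  # reading frame anchored at germline V position 1
  frame_start <- v_aln$query_start - ((v_aln$subject_start - 1L) %% 3L)
  frame_start <- max(1L, frame_start)
  orf_end <- if (!is.null(annotation$assignment$j)) {
    annotation$assignment$j$alignment$query_end
  } else v_aln$query_end
  orf <- substr(annotation$seq, frame_start, orf_end)
  orf <- substr(orf, 1L, (nchar(orf) %/% 3L) * 3L)
  if (nzchar(orf)) {
    codons <- substring(orf, seq(1L, nchar(orf), 3L), seq(3L, nchar(orf), 3L))
    if (any(codons %in% STOP_CODONS)) reasons <- c(reasons, "stop_codon")
  }
  list(productive = length(reasons) == 0L, reasons = reasons)
}

#' Full immunological annotation of one chain sequence
#'
#' Convenience wrapper running [assign_segments()], [annotate_regions()],
#' [call_mutations()], [assign_isotype()] and [classify_productive()].
#'
#' @inheritParams assign_segments
#' @param min_c_len,min_c_identity see [assign_isotype()].
#' @return a `chain_annotation` list: `seq`, `assignment`, `regions`,
#'   `junction`, `junction_nt`, `junction_aa`, `mutations`, `isotype`,
#'   `productive`, `reasons`, `flags`.
#' @export
annotate_chain <- function(seq, ref, scheme = scoring_scheme(),
                           min_scores = default_min_scores(),
                           min_c_len = 30L, min_c_identity = 0.95) {
  seq <- toupper(seq)
  assignment <- assign_segments(seq, ref, scheme, min_scores)
  if (assignment$unannotatable) {
    return(structure(list(seq = seq, assignment = assignment,
                          regions = NULL, junction = NULL,
                          junction_nt = NA_character_,
                          junction_aa = NA_character_,
                          mutations = empty_mutations(),
                          isotype = NA_character_, productive = FALSE,
                          reasons = "unannotatable", flags = character(0)),
                     class = "chain_annotation"))
  }
  reg <- annotate_regions(seq, assignment, ref)
  mutations <- call_mutations(seq, assignment, ref)
  isotype <- assign_isotype(seq, assignment, ref, min_c_len, min_c_identity,
                            scheme)
  ann <- list(seq = seq, assignment = assignment, regions = reg$regions,
              junction = reg$junction, flags = reg$flags)
  prod <- classify_productive(ann)
  junction_nt <- if (!is.null(reg$junction)) {
    substr(seq, reg$junction[["start"]], reg$junction[["end"]])
  } else NA_character_
  ann$junction_nt <- junction_nt
  ann$junction_aa <- if (!is.na(junction_nt)) translate_nt(junction_nt) else
    NA_character_
  ann$mutations <- mutations
  ann$isotype <- isotype
  ann$productive <- prod$productive
  ann$reasons <- prod$reasons
  structure(ann, class = "chain_annotation")
}
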