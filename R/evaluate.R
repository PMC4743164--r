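#' Benchmark pipeline stages against a simulation's truth tables
#'
#' The synthetic-data generator records the origin of every read and the
#' exact transcript of every cell, so each pipeline stage can be scored
#' against known truth. These helpers power the package's property tests and
#' the reproduction script; they are also the recommended way to validate
#' parameter changes (scoring, thresholds, window sizes) before applying
#' them to real data.
#'
#' `demux_accuracy()` demultiplexes the simulated reads and compares every
#' read's decoded well against its true well.
#'
#' @param sim a [simulate_repertoire()] result.
#' @return `demux_accuracy()`: list with `n_reads`, `frac_both` (fraction of
#'   reads with both tags identified), `frac_correct` (fraction of all reads
#'   decoded to their true well) and `n_wrong_well` (status-`both` reads
#'   decoded to a well other than the truth).
#' @export
demux_accuracy <- function(sim) {
  tags <- identify_tags(sim$reads, sim$scheme)
  dec <- decode_events(tags, sim$layout, sim$experiment_id)
  truth <- sim$truth$reads$event_id
  assigned <- !is.na(dec$event_id)
  list(n_reads = nrow(sim$reads),
       frac_both = mean(tags$status == "both"),
       frac_correct = mean(assigned & dec$event_id == truth, na.rm = TRUE),
       n_wrong_well = sum(assigned & dec$event_id != truth))
}

truth_read_fields <- function(sim, idx, field) {
  tr <- sim$truth$reads
  tc <- sim$truth$cells
  m <- match(tr$event_id[idx], tc$event_id)
  heavy <- tr$locus[idx] == "IGH"
  second <- tr$transcript_no[idx] == 2L
  out <- tc[[paste0("light_", field)]][m]
  if (field %in% c("v", "j", "c", "sequence")) {
    out[heavy] <- ifelse(second[heavy],
                         tc[[paste0("heavy2_", field)]][m][heavy],
                         tc[[paste0("heavy_", field)]][m][heavy])
  }
  out
}

#' @rdname demux_accuracy
#' @param ref the [germline_reference()] the simulation used.
#' @param max_reads optional cap on the number of demultiplexed reads scored
#'   (reads are taken in input order).
#' @return `assignment_accuracy()`: list with `n_scored` plus gene-level
#'   `v_gene_accuracy` and `j_gene_accuracy` and `isotype_accuracy` against
#'   the truth table.
#' @export
assignment_accuracy <- function(sim, ref, max_reads = NULL) {
  tags <- identify_tags(sim$reads, sim$scheme)
  dec <- decode_events(tags, sim$layout, sim$experiment_id)
  idx <- which(!is.na(dec$event_id))
  if (!is.null(max_reads)) idx <- head(idx, max_reads)
  plen <- nchar(sim$scheme$proximal[[1L]])
  v_ok <- j_ok <- c_ok <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    seqv <- substr(sim$reads$sequence[i], dec$proximal_offset[i] + plen,
                   dec$distal_offset[i] - 1L)
    a <- assign_segments(seqv, ref)
    v_ok[k] <- !a$unannotatable &&
      identical(ig_gene(a$v$segment_id),
                ig_gene(truth_read_fields(sim, i, "v")))
    j_ok[k] <- !is.null(a$j) &&
      identical(ig_gene(a$j$segment_id),
                ig_gene(truth_read_fields(sim, i, "j")))
    iso <- assign_isotype(seqv, a, ref)
    c_ok[k] <- identical(iso, ig_gene(truth_read_fields(sim, i, "c")))
  }
  list(n_scored = length(idx),
       v_gene_accuracy = mean(v_ok),
       j_gene_accuracy = mean(j_ok),
       isotype_accuracy = mean(c_ok))
}

true_transcripts_for <- function(sim, event_id, locus) {
  tc <- sim$truth$cells
  cell <- tc[tc$event_id == event_id, ]
  if (!nrow(cell)) return(character(0))
  if (locus == "IGH") {
    out <- cell$heavy_sequence
    if (isTRUE(cell$is_doublet)) out <- c(out, cell$heavy2_sequence)
    out
  } else if (identical(cell$light_locus, locus)) {
    cell$light_sequence
  } else character(0)
}

#' @rdname demux_accuracy
#' @param store an `ig_store` holding the pipeline results for `sim`.
#' @param min_reads only rank-1 consensus chains built from at least this
#'   many reads are scored (error correction needs read redundancy).
#' @return `consensus_recovery()`: list with `n_chains` and `frac_exact`,
#'   the fraction of scored chains whose consensus equals the true
#'   transcript base for base.
#' @export
consensus_recovery <- function(store, sim, min_reads = 5L) {
  cons <- store_get(store, "consensus")
  r1 <- cons[cons$rank == 1L & cons$n_reads >= min_reads, , drop = FALSE]
  ok <- vapply(seq_len(nrow(r1)), function(i) {
    r1$sequence[i] %in% true_transcripts_for(sim, r1$event_id[i],
                                             r1$locus[i])
  }, TRUE)
  list(n_chains = nrow(r1), frac_exact = mean(ok))
}

#' @rdname demux_accuracy
#' @return `doublet_recovery()`: list with `n_doublet_wells` and
#'   `frac_recovered`, the fraction of wells carrying two heavy transcripts
#'   whose rank-1/rank-2 consensus pair identifies both true gene-level V-J
#'   combinations.
#' @export
doublet_recovery <- function(store, sim) {
  ann <- store_get(store, "chain_annotations")
  db <- sim$truth$cells[sim$truth$cells$is_doublet, , drop = FALSE]
  ok <- vapply(seq_len(nrow(db)), function(i) {
    h <- ann[ann$event_id == db$event_id[i] & ann$locus == "IGH", ,
             drop = FALSE]
    truth_keys <- c(paste(ig_gene(db$heavy_v[i]), ig_gene(db$heavy_j[i])),
                    paste(ig_gene(db$heavy2_v[i]), ig_gene(db$heavy2_j[i])))
    nrow(h) == 2L && setequal(paste(ig_gene(h$v_call), ig_gene(h$j_call)),
                              truth_keys)
  }, TRUE)
  list(n_doublet_wells = nrow(db), frac_recovered = mean(ok))
}

#' @rdname demux_accuracy
#' @return `shm_recovery()`: list with `n_chains` and `frac_exact`, the
#'   fraction of rank-1 chains whose called V substitution set (germline
#'   position, from-base, to-base) equals the injected set.
#' @export
shm_recovery <- function(store, sim) {
  cons <- store_get(store, "consensus")
  muts <- store_get(store, "mutations")
  r1 <- cons[cons$rank == 1L, , drop = FALSE]
  tc <- sim$truth$cells
  ok <- vapply(seq_len(nrow(r1)), function(i) {
    cell <- tc[tc$event_id == r1$event_id[i], ]
    if (!nrow(cell)) return(FALSE)
    if (r1$locus[i] == "IGH") {
      truth_v <- cell$heavy_v; truth_mut <- cell$heavy_mutations
    } else {
      if (!identical(cell$light_locus, r1$locus[i])) return(FALSE)
      truth_v <- cell$light_v; truth_mut <- cell$light_mutations
    }
    truth <- decode_mutations(truth_mut)
    got <- muts[muts$consensus_id == r1$consensus_id[i] &
                  muts$kind == "substitution" &
                  muts$segment_id == truth_v, , drop = FALSE]
    nrow(got) == nrow(truth) &&
      identical(sort(paste(got$germline_pos, got$germline_base,
                           got$query_base)),
                sort(paste(truth$germline_pos, truth$germline_base,
                           truth$query_base)))
  }, TRUE)
  list(n_chains = nrow(r1), frac_exact = mean(ok))
}

#' @rdname demux_accuracy
#' @return `germline_self_mutations()`: the maximum mutation count over all
#'   reference V segments re-annotated against their own reference (0 for a
#'   correct aligner).
#' @export
germline_self_mutations <- function(ref) {
  vs <- ref$segments[ref$segments$segment_type == "V", , drop = FALSE]
  max(vapply(seq_len(nrow(vs)), function(i) {
    a <- assign_segments(vs$sequence[i], ref)
    nrow(call_mutations(vs$sequence[i], a, ref))
  }, 1L))
}
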