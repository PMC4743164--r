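STORE_VERSION <- "igwell-store 1"

# Four-section schema: 1) raw reads, 2) single-cell consensus annotations,
# 3) metadata + FC index, 4) germline reference. Column prototypes double as
# the TSV read/write contract.
STORE_SCHEMA <- list(
  reads = list(section = 1L, cols = c(read_id = "character",
    sequence = "character", quality = "character")),
  tag_assignments = list(section = 1L, cols = c(read_id = "character",
    proximal_tag = "character", proximal_offset = "integer",
    proximal_mismatches = "integer", distal_tag = "character",
    distal_offset = "integer", distal_mismatches = "integer",
    status = "character", plate = "integer", row = "character",
    col = "integer", event_id = "character",
    unassigned_reason = "character")),
  consensus = list(section = 2L, cols = c(consensus_id = "character",
    event_id = "character", locus = "character", rank = "integer",
    sequence = "character", n_reads = "integer",
    column_agreement = "numeric", source = "character")),
  segment_assignments = list(section = 2L, cols = c(
    consensus_id = "character", segment_type = "character",
    segment_id = "character", score = "integer", query_start = "integer",
    query_end = "integer", subject_start = "integer",
    subject_end = "integer", identity = "numeric", cigar = "character")),
  mutations = list(section = 2L, cols = c(consensus_id = "character",
    segment_id = "character", germline_pos = "integer",
    germline_base = "character", query_base = "character",
    kind = "character", region = "character")),
  chain_annotations = list(section = 2L, cols = c(consensus_id = "character",
    event_id = "character", locus = "character", rank = "integer",
    v_call = "character", d_call = "character", j_call = "character",
    c_call = "character", junction = "character",
    junction_aa = "character", junction_start = "integer",
    junction_end = "integer", isotype = "character",
    productive = "logical", reasons = "character",
    mutation_count = "integer", regions = "character",
    flags = "character")),
  donors = list(section = 3L, cols = c(donor_id = "character")),
  samples = list(section = 3L, cols = c(sample_id = "character",
    donor_id = "character")),
  sort_events = list(section = 3L, cols = c(event_id = "character",
    plate = "integer", row = "character", col = "integer",
    donor_id = "character", sample_id = "character",
    sort_date = "character", empty_well = "logical")),
  fc_index_values = list(section = 3L, cols = c(event_id = "character",
    channel = "character", value = "numeric", reagent = "character",
    fluorochrome = "character")),
  germline_segments = list(section = 4L, cols = c(segment_id = "character",
    gene = "character", family = "character", locus = "character",
    segment_type = "character", sequence = "character")),
  region_maps = list(section = 4L, cols = c(segment_id = "character",
    region = "character", start = "integer", end = "integer"))
)

empty_table <- function(name) {
  cols <- STORE_SCHEMA[[name]]$cols
  df <- lapply(cols, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

table_path <- function(store, name) file.path(store$path, paste0(name, ".tsv"))

#' Initialize (or reopen) an igwell datastore
#'
#' Creates a directory-backed relational datastore whose tables mirror the
#' pipeline's four data sections: (1) raw sequencing reads and tag
#' assignments, (2) single-cell consensus sequences with their segment
#' assignments, mutations and chain annotations, (3) metadata and
#' flow-cytometry index data, (4) germline reference segments and region
#' maps. One TSV per table; a version stamp guards compatibility.
#' Re-initializing an existing compatible store is a no-op that reopens it;
#' a store stamped with a different version is a fatal error.
#'
#' @param path store directory.
#' @return an `ig_store` handle.
#' @export
init_store <- function(path) {
  vfile <- file.path(path, "VERSION")
  exists_already <- file.exists(vfile)
  if (exists_already) {
    v <- readLines(vfile, n = 1L)
    if (!identical(v, STORE_VERSION)) {
      stop("incompatible store version at ", path, ": found '", v,
           "', expected '", STORE_VERSION, "'")
    }
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$tables <- new.env(parent = emptyenv())
  class(store) <- "ig_store"
  if (!exists_already) {
    writeLines(STORE_VERSION, vfile)
    for (name in names(STORE_SCHEMA)) {
      store_set(store, name, empty_table(name))
    }
  }
  store
}

#' @export
print.ig_store <- function(x, ...) {
  counts <- vapply(names(STORE_SCHEMA), function(n) nrow(store_get(x, n)), 1L)
  cat("ig_store at ", x$path, "\n", sep = "")
  for (s in 1:4) {
    in_s <- names(STORE_SCHEMA)[vapply(STORE_SCHEMA, `[[`, 1L, "section") == s]
    cat("  section ", s, ": ",
        paste(sprintf("%s (%d)", in_s, counts[in_s]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read and write store tables
#'
#' `store_get()` returns a table as a data.frame (cached in memory after
#' first read); `store_set()` replaces a table; `store_append()` appends
#' rows. Unknown table names are an error; columns are coerced to the schema
#' prototype.
#'
#' @param store an `ig_store`.
#' @param name table name (see the package vignette for the schema).
#' @return `store_get()`: data.frame.
#' @export
store_get <- function(store, name) {
  if (!name %in% names(STORE_SCHEMA)) stop("unknown store table: ", name)
  if (!is.null(store$tables[[name]])) return(store$tables[[name]])
  p <- table_path(store, name)
  cols <- STORE_SCHEMA[[name]]$cols
  df <- if (file.exists(p) && length(readLines(p, n = 2L)) > 1L) {
    read.delim(p, stringsAsFactors = FALSE, colClasses = unname(cols),
               na.strings = "NA", quote = "")
  } else {
    empty_table(name)
  }
  store$tables[[name]] <- df
  df
}

#' @rdname store_get
#' @param df replacement / appended rows (schema columns).
#' @export
store_set <- function(store, name, df) {
  if (!name %in% names(STORE_SCHEMA)) stop("unknown store table: ", name)
  cols <- STORE_SCHEMA[[name]]$cols
  missing <- setdiff(names(cols), names(df))
  for (m in missing) df[[m]] <- vector(cols[[m]], 1L)[NA]
  df <- df[, names(cols), drop = FALSE]
  for (k in names(cols)) {
    df[[k]] <- switch(cols[[k]], character = as.character(df[[k]]),
                      integer = as.integer(df[[k]]),
                      numeric = as.numeric(df[[k]]),
                      logical = as.logical(df[[k]]))
  }
  rownames(df) <- NULL
  store$tables[[name]] <- df
  write.table(df, table_path(store, name), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(store)
}

#' @rdname store_get
#' @export
store_append <- function(store, name, df) {
  store_set(store, name, rbind(store_get(store, name),
                               df[, intersect(names(df),
                                              names(STORE_SCHEMA[[name]]$cols)),
                                  drop = FALSE]))
}

#' Load a germline reference into store section 4
#'
#' @param store an `ig_store`.
#' @param ref a [germline_reference()].
#' @return the store, invisibly.
#' @export
store_load_reference <- function(store, ref) {
  store_set(store, "germline_segments", ref$segments)
  store_set(store, "region_maps", ref$region_map)
  invisible(store)
}

#' Load metadata and FC index CSVs into store section 3
#'
#' The metadata CSV carries one row per sorted well (columns `plate`, `row`,
#' `col`, `donor`, `sample`, `sort_date`, `empty_well`); the FC index CSV
#' carries one row per sorted well with `plate`, `row`, `col` and one column
#' per fluorescence channel. Wells are resolved to event ids through the
#' plate layout; FC rows for wells absent from the layout are counted as
#' unmatched, not fatal.
#'
#' @param store an `ig_store`.
#' @param metadata_csv,fc_csv CSV paths (or data.frames).
#' @param layout a [plate_layout()].
#' @param experiment_id experiment label used in event ids.
#' @param channel_labels optional data.frame (channel, reagent,
#'   fluorochrome) describing the FC channels.
#' @return list with `n_metadata`, `n_fc`, `n_unmatched_wells`.
#' @export
load_metadata_and_fc <- function(store, metadata_csv, fc_csv, layout,
                                 experiment_id = "exp1",
                                 channel_labels = NULL) {
  meta <- if (is.character(metadata_csv)) {
    read.csv(metadata_csv, stringsAsFactors = FALSE,
             colClasses = c(row = "character"))
  } else metadata_csv
  fc <- if (is.character(fc_csv)) {
    read.csv(fc_csv, stringsAsFactors = FALSE,
             colClasses = c(row = "character"))
  } else fc_csv
  lkey <- paste(layout$plate, layout$row, layout$col, sep = "\r")

  mkey <- paste(meta$plate, meta$row, meta$col, sep = "\r")
  m_ok <- mkey %in% lkey
  meta_ok <- meta[m_ok, , drop = FALSE]
  sort_events <- data.frame(
    event_id = make_event_id(experiment_id, meta_ok$plate, meta_ok$row,
                             meta_ok$col),
    plate = meta_ok$plate, row = meta_ok$row, col = meta_ok$col,
    donor_id = meta_ok$donor, sample_id = meta_ok$sample,
    sort_date = meta_ok$sort_date, empty_well = meta_ok$empty_well,
    stringsAsFactors = FALSE
  )
  store_set(store, "sort_events", sort_events)
  store_set(store, "donors",
            data.frame(donor_id = sort(unique(meta_ok$donor)),
                       stringsAsFactors = FALSE))
  samples <- unique(data.frame(sample_id = meta_ok$sample,
                               donor_id = meta_ok$donor,
                               stringsAsFactors = FALSE))
  store_set(store, "samples", samples[order(samples$sample_id), ])

  fkey <- paste(fc$plate, fc$row, fc$col, sep = "\r")
  f_ok <- fkey %in% lkey
  channels <- setdiff(names(fc), c("plate", "row", "col"))
  fc_ok <- fc[f_ok, , drop = FALSE]
  long <- do.call(rbind, lapply(channels, function(ch) {
    data.frame(
      event_id = make_event_id(experiment_id, fc_ok$plate, fc_ok$row,
                               fc_ok$col),
      channel = ch, value = as.numeric(fc_ok[[ch]]),
      reagent = NA_character_, fluorochrome = NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(long)) long <- empty_table("fc_index_values")
  if (!is.null(channel_labels)) {
    idx <- match(long$channel, channel_labels$channel)
    long$reagent <- channel_labels$reagent[idx]
    long$fluorochrome <- channel_labels$fluorochrome[idx]
  }
  long <- long[order(long$event_id, long$channel), ]
  store_set(store, "fc_index_values", long)
  list(n_metadata = nrow(meta_ok), n_fc = nrow(fc_ok),
       n_unmatched_wells = sum(!m_ok) + sum(!f_ok))
}

fc_wide <- function(store) {
  fc <- store_get(store, "fc_index_values")
  if (!nrow(fc)) {
    return(data.frame(event_id = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(event_id = sort(unique(fc$event_id)),
                    stringsAsFactors = FALSE)
  for (ch in sort(unique(fc$channel))) {
    sub <- fc[fc$channel == ch, ]
    out[[ch]] <- sub$value[match(out$event_id, sub$event_id)]
  }
  out
}

#' Join per-event heavy and light chain information into cell records
#'
#' One record per event with at least one rank-1 consensus: the rank-1 heavy
#' chain annotation, the rank-1 light chain (kappa or lambda), isotype,
#' productivity, read support, FC channel values and metadata. When both a
#' kappa and a lambda rank-1 consensus exist the light chain with the higher
#' read support wins and `light_conflict` is set. Cells lacking one chain
#' are returned with `pairing` set to `heavy_only` / `light_only`.
#'
#' @param store an `ig_store`.
#' @param donor,isotype,light_locus optional filters (exact match).
#' @param productive optional logical filter on heavy-chain productivity.
#' @return data.frame of cell records, one row per event.
#' @export
query_cells <- function(store, donor = NULL, isotype = NULL,
                        light_locus = NULL, productive = NULL) {
  ann <- store_get(store, "chain_annotations")
  cons <- store_get(store, "consensus")
  ann <- ann[ann$rank == 1L, , drop = FALSE]
  ann$n_reads <- cons$n_reads[match(ann$consensus_id, cons$consensus_id)]
  events <- sort(unique(ann$event_id))
  if (!length(events)) return(empty_cells())
  heavy <- ann[ann$locus == "IGH", , drop = FALSE]
  light <- ann[ann$locus %in% c("IGK", "IGL"), , drop = FALSE]
  rows <- lapply(events, function(ev) {
    h <- heavy[heavy$event_id == ev, , drop = FALSE]
    l <- light[light$event_id == ev, , drop = FALSE]
    conflict <- nrow(l) > 1L
    if (conflict) {
      l <- l[order(-l$n_reads, l$locus), , drop = FALSE][1L, , drop = FALSE]
    }
    h <- if (nrow(h)) h[1L, ] else NULL
    l <- if (nrow(l)) l[1L, ] else NULL
    data.frame(
      event_id = ev,
      pairing = if (!is.null(h) && !is.null(l)) "paired"
                else if (!is.null(h)) "heavy_only" else "light_only",
      light_conflict = conflict,
      heavy_consensus_id = if (is.null(h)) NA_character_ else h$consensus_id,
      heavy_v_call = if (is.null(h)) NA_character_ else h$v_call,
      heavy_d_call = if (is.null(h)) NA_character_ else h$d_call,
      heavy_j_call = if (is.null(h)) NA_character_ else h$j_call,
      heavy_junction = if (is.null(h)) NA_character_ else h$junction,
      heavy_productive = if (is.null(h)) NA else h$productive,
      heavy_mutation_count = if (is.null(h)) NA_integer_ else
        h$mutation_count,
      heavy_n_reads = if (is.null(h)) NA_integer_ else h$n_reads,
      isotype = if (is.null(h)) NA_character_ else h$isotype,
      light_consensus_id = if (is.null(l)) NA_character_ else l$consensus_id,
      light_locus = if (is.null(l)) NA_character_ else l$locus,
      light_v_call = if (is.null(l)) NA_character_ else l$v_call,
      light_j_call = if (is.null(l)) NA_character_ else l$j_call,
      light_junction = if (is.null(l)) NA_character_ else l$junction,
      light_productive = if (is.null(l)) NA else l$productive,
      light_n_reads = if (is.null(l)) NA_integer_ else l$n_reads,
      stringsAsFactors = FALSE
    )
  })
  cells <- do.call(rbind, rows)
  se <- store_get(store, "sort_events")
  idx <- match(cells$event_id, se$event_id)
  cells$donor <- se$donor_id[idx]
  cells$sample <- se$sample_id[idx]
  fcw <- fc_wide(store)
  if (ncol(fcw) > 1L) {
    fidx <- match(cells$event_id, fcw$event_id)
    for (ch in setdiff(names(fcw), "event_id")) cells[[ch]] <- fcw[[ch]][fidx]
  }
  cells$heavy_v_gene <- ig_gene(cells$heavy_v_call)
  cells$heavy_v_family <- ig_family(cells$heavy_v_call)
  cells$heavy_j_gene <- ig_gene(cells$heavy_j_call)
  cells$heavy_j_family <- ig_family(cells$heavy_j_call)
  cells$light_v_gene <- ig_gene(cells$light_v_call)
  cells$light_v_family <- ig_family(cells$light_v_call)
  cells$light_j_gene <- ig_gene(cells$light_j_call)
  cells$light_j_family <- ig_family(cells$light_j_call)
  if (!is.null(donor)) cells <- cells[!is.na(cells$donor) &
                                        cells$donor %in% donor, ]
  if (!is.null(isotype)) cells <- cells[!is.na(cells$isotype) &
                                          cells$isotype %in% isotype, ]
  if (!is.null(light_locus)) {
    cells <- cells[!is.na(cells$light_locus) &
                     cells$light_locus %in% light_locus, ]
  }
  if (!is.null(productive)) {
    cells <- cells[!is.na(cells$heavy_productive) &
                     cells$heavy_productive == productive, ]
  }
  rownames(cells) <- NULL
  cells
}

empty_cells <- function() {
  data.frame(event_id = character(), pairing = character(),
             light_conflict = logical(), stringsAsFactors = FALSE)
}

#' Referential-integrity and conservation audit
#'
#' Verifies the foreign-key relations of the four-section schema (every tag
#' assignment references a stored read; every consensus an existing sort
#' event; every mutation an existing consensus and germline segment; every
#' FC value an existing sort event; every region map a germline V segment)
#' plus the pairing conservation identity (paired + heavy-only + light-only
#' = events with at least one rank-1 consensus).
#'
#' @param store an `ig_store`.
#' @return data.frame with columns `check`, `pass`, `detail`; attribute
#'   `ok` is TRUE when all checks pass.
#' @export
audit_store <- function(store) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  reads <- store_get(store, "reads")
  tags <- store_get(store, "tag_assignments")
  cons <- store_get(store, "consensus")
  sega <- store_get(store, "segment_assignments")
  muts <- store_get(store, "mutations")
  ann <- store_get(store, "chain_annotations")
  se <- store_get(store, "sort_events")
  fc <- store_get(store, "fc_index_values")
  gs <- store_get(store, "germline_segments")
  rmaps <- store_get(store, "region_maps")

  add("tag_assignments.read_id in reads",
      all(tags$read_id %in% reads$read_id),
      sprintf("%d orphans", sum(!tags$read_id %in% reads$read_id)))
  if (nrow(se)) {
    add("consensus.event_id in sort_events",
        all(cons$event_id %in% se$event_id),
        sprintf("%d orphans", sum(!cons$event_id %in% se$event_id)))
    add("fc_index_values.event_id in sort_events",
        all(fc$event_id %in% se$event_id),
        sprintf("%d orphans", sum(!fc$event_id %in% se$event_id)))
  }
  add("segment_assignments.consensus_id in consensus",
      all(sega$consensus_id %in% cons$consensus_id), "")
  add("segment_assignments.segment_id in germline_segments",
      all(sega$segment_id %in% gs$segment_id), "")
  add("mutations.consensus_id in consensus",
      all(muts$consensus_id %in% cons$consensus_id), "")
  add("mutations.segment_id in germline_segments",
      all(muts$segment_id %in% gs$segment_id), "")
  add("chain_annotations.consensus_id in consensus",
      all(ann$consensus_id %in% cons$consensus_id), "")
  add("region_maps.segment_id in germline V segments",
      all(rmaps$segment_id %in%
            gs$segment_id[gs$segment_type == "V"]), "")
  add("consensus rank-2 implies rank-1",
      all(vapply(which(cons$rank == 2L), function(i) {
        any(cons$rank == 1L & cons$event_id == cons$event_id[i] &
              cons$locus == cons$locus[i])
      }, TRUE)), "")
  cells <- query_cells(store)
  n_events <- length(unique(cons$event_id[cons$rank == 1L]))
  add("pairing conservation",
      sum(cells$pairing == "paired") + sum(cells$pairing == "heavy_only") +
        sum(cells$pairing == "light_only") == n_events,
      sprintf("%d cells vs %d events", nrow(cells), n_events))
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}

#' Export chain annotations as an AIRR-style rearrangement TSV
#'
#' One row per consensus chain with the community-standard column names
#' (`sequence_id`, `sequence`, `locus`, `v_call`, `d_call`, `j_call`,
#' `c_call`, `junction`, `junction_aa`, `productive`, plus event linkage,
#' read support and mutation count). Rows are sorted by `sequence_id` so
#' exports are byte-stable.
#'
#' @param store an `ig_store`.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_airr <- function(store, path) {
  ann <- store_get(store, "chain_annotations")
  cons <- store_get(store, "consensus")
  idx <- match(ann$consensus_id, cons$consensus_id)
  out <- data.frame(
    sequence_id = ann$consensus_id,
    cell_id = ann$event_id,
    locus = ann$locus,
    consensus_rank = ann$rank,
    sequence = cons$sequence[idx],
    v_call = ann$v_call, d_call = ann$d_call, j_call = ann$j_call,
    c_call = ann$c_call,
    junction = ann$junction, junction_aa = ann$junction_aa,
    productive = ann$productive,
    isotype = ann$isotype,
    mutation_count = ann$mutation_count,
    consensus_count = cons$n_reads[idx],
    regions = ann$regions,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sequence_id), ]
  rownames(out) <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(out)
}

#' Export cell-level records as TSV
#'
#' @param store an `ig_store`.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame (see [query_cells()]).
#' @export
export_cells <- function(store, path) {
  cells <- query_cells(store)
  cells <- cells[order(cells$event_id), , drop = FALSE]
  rownames(cells) <- NULL
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(cells)
}
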