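#' Pipeline configuration
#'
#' Collects paths, objects and parameters for one end-to-end run. Two
#' branches exist: `"ngs"` processes raw plate-barcoded reads
#' (demultiplexing, per-read annotation, per-cell consensus, annotation,
#' linkage), `"single_cell"` ingests sequences that are already at
#' single-cell level (per-cell FASTA; tag identification and consensus
#' building are skipped). Inputs may be given as file paths (FASTQ / TSV /
#' CSV) or as the in-memory objects the rest of the package uses.
#'
#' @param branch `"ngs"` or `"single_cell"`.
#' @param store_path directory for the datastore.
#' @param out_dir directory for exports, QC series and the run summary.
#' @param ref a [germline_reference()], or a directory containing
#'   `v.fasta`, `d.fasta`, `j.fasta`, `c.fasta`, `regions.tsv`.
#' @param reads FASTQ path or data.frame (`read_id`, `sequence`, `quality`);
#'   ngs branch only.
#' @param scheme barcode scheme TSV path or [barcode_scheme()]; ngs only.
#' @param layout layout TSV path or [plate_layout()]; ngs only.
#' @param per_cell_fasta per-cell FASTA path; single_cell branch only.
#' @param metadata,fc metadata / FC index CSV paths or data.frames
#'   (optional).
#' @param experiment_id experiment label used in event ids.
#' @param seed integer seed covering every stochastic step (currently the
#'   consensus subsampling cap).
#' @param scoring a [scoring_scheme()].
#' @param min_scores see [assign_segments()].
#' @param min_c_len,min_c_identity see [assign_isotype()].
#' @param min_secondary_support see [build_secondary()].
#' @param max_consensus_reads cap on reads per consensus group.
#' @param contamination_threshold see [compute_qc()].
#' @param render_plots also render QC plot images (TSV series are always
#'   written).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(branch = c("ngs", "single_cell"), store_path,
                            out_dir, ref, reads = NULL, scheme = NULL,
                            layout = NULL, per_cell_fasta = NULL,
                            metadata = NULL, fc = NULL,
                            experiment_id = "exp1", seed = 1L,
                            scoring = scoring_scheme(),
                            min_scores = default_min_scores(),
                            min_c_len = 30L, min_c_identity = 0.95,
                            min_secondary_support = 2L,
                            max_consensus_reads = 500L,
                            contamination_threshold = 5L,
                            render_plots = TRUE) {
  branch <- match.arg(branch)
  check_path <- function(x, what) {
    if (is.character(x) && !file.exists(x)) {
      stop("configured ", what, " path does not exist: ", x)
    }
    x
  }
  if (branch == "ngs") {
    if (is.null(reads) || is.null(scheme) || is.null(layout)) {
      stop("ngs branch requires reads, scheme and layout")
    }
    check_path(reads, "reads"); check_path(scheme, "scheme")
    check_path(layout, "layout")
  } else {
    if (is.null(per_cell_fasta)) {
      stop("single_cell branch requires per_cell_fasta")
    }
    check_path(per_cell_fasta, "per_cell_fasta")
  }
  check_path(metadata, "metadata"); check_path(fc, "fc")
  if (is.character(ref)) check_path(ref, "reference")
  structure(list(branch = branch, store_path = store_path,
                 out_dir = out_dir, ref = ref, reads = reads,
                 scheme = scheme, layout = layout,
                 per_cell_fasta = per_cell_fasta, metadata = metadata,
                 fc = fc, experiment_id = experiment_id,
                 seed = as.integer(seed), scoring = scoring,
                 min_scores = min_scores, min_c_len = min_c_len,
                 min_c_identity = min_c_identity,
                 min_secondary_support = min_secondary_support,
                 max_consensus_reads = max_consensus_reads,
                 contamination_threshold = contamination_threshold,
                 render_plots = render_plots),
            class = "pipeline_config")
}

resolve_ref <- function(config) {
  if (inherits(config$ref, "germline_reference")) return(config$ref)
  d <- config$ref
  dfa <- file.path(d, "d.fasta")
  load_reference(file.path(d, "v.fasta"),
                 if (file.exists(dfa)) dfa else NULL,
                 file.path(d, "j.fasta"), file.path(d, "c.fasta"),
                 file.path(d, "regions.tsv"))
}

resolve_scheme <- function(config) {
  if (inherits(config$scheme, "barcode_scheme")) config$scheme
  else read_barcode_scheme(config$scheme)
}

resolve_layout <- function(config) {
  if (is.null(config$layout)) NULL
  else if (inherits(config$layout, "plate_layout")) config$layout
  else read_plate_layout(config$layout)
}

resolve_reads <- function(config) {
  if (is.data.frame(config$reads)) config$reads else read_fastq(config$reads)
}

aux_path <- function(store, name) file.path(store$path, paste0(name, ".tsv"))

aux_write <- function(store, name, df) {
  write.table(df, aux_path(store, name), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
}

aux_read <- function(store, name, colClasses) {
  read.delim(aux_path(store, name), stringsAsFactors = FALSE,
             colClasses = colClasses, na.strings = "NA", quote = "")
}

annotate_read_table <- function(seqs, read_ids, event_ids, config, ref) {
  n <- length(seqs)
  v_gene <- rep(NA_character_, n); j_gene <- rep(NA_character_, n)
  locus <- rep(NA_character_, n); v_score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- assign_segments(seqs[i], ref, config$scoring, config$min_scores)
    if (!a$unannotatable) {
      v_gene[i] <- ig_gene(a$v$segment_id)
      v_score[i] <- a$v$alignment$score
      locus[i] <- a$locus
      if (!is.null(a$j)) j_gene[i] <- ig_gene(a$j$segment_id)
    }
  }
  data.frame(read_id = read_ids, event_id = event_ids, locus = locus,
             v_gene = v_gene, j_gene = j_gene, v_score = v_score,
             trimmed_seq = seqs, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the configured branch's stages in order, stamping each completed
#' stage in the store so an interrupted run resumes where it stopped.
#' Stages (ngs branch): reference loading, demultiplexing, per-read segment
#' assignment, per-cell consensus building, consensus annotation, metadata /
#' FC linkage, QC + export. The single_cell branch replaces the first four
#' with per-cell FASTA ingestion. Exports (`rearrangements.tsv`,
#' `cells.tsv`, QC TSV series) are sorted, so identical configuration and
#' seed reproduce them byte for byte. A machine-readable run summary with
#' per-stage counts and the full parameter echo is written as JSON.
#'
#' @param config a [pipeline_config()].
#' @param stop_after stop after this stage completes (for resuming later;
#'   mainly used to exercise resumability).
#' @return invisibly, a list with `store`, `summary` (the run summary list)
#'   and `paths` of the exports; `NULL` summary when stopped early.
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  store <- init_store(config$store_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp_file <- file.path(store$path, "stages")
  done <- if (file.exists(stamp_file)) readLines(stamp_file) else character(0)
  stopped <- FALSE
  run_stage <- function(name, fun) {
    if (stopped) return(invisible(NULL))
    if (!name %in% done) {
      fun()
      cat(name, "\n", file = stamp_file, append = TRUE, sep = "")
    }
    if (!is.null(stop_after) && identical(stop_after, name)) {
      stopped <<- TRUE
    }
    invisible(NULL)
  }
  ref <- resolve_ref(config)
  layout <- resolve_layout(config)

  run_stage("reference", function() store_load_reference(store, ref))

  if (config$branch == "ngs") {
    scheme <- resolve_scheme(config)
    run_stage("demux", function() {
      reads <- resolve_reads(config)
      store_set(store, "reads", reads)
      tags <- identify_tags(reads, scheme)
      dec <- decode_events(tags, layout, config$experiment_id)
      store_set(store, "tag_assignments", dec)
    })
    run_stage("read_annotation", function() {
      dec <- store_get(store, "tag_assignments")
      reads <- store_get(store, "reads")
      ok <- !is.na(dec$event_id)
      sub <- dec[ok, , drop = FALSE]
      seqs <- reads$sequence[match(sub$read_id, reads$read_id)]
      plen <- nchar(scheme$proximal[[1L]])
      trimmed <- substr(seqs, sub$proximal_offset + plen,
                        sub$distal_offset - 1L)
      aux_write(store, "read_annotations",
                annotate_read_table(trimmed, sub$read_id, sub$event_id,
                                    config, ref))
    })
    run_stage("consensus", function() {
      ra <- aux_read(store, "read_annotations",
                     c(read_id = "character", event_id = "character",
                       locus = "character", v_gene = "character",
                       j_gene = "character", v_score = "numeric",
                       trimmed_seq = "character"))
      cons_rows <- list()
      keys <- unique(ra[!is.na(ra$locus), c("event_id", "locus")])
      keys <- keys[order(keys$event_id, keys$locus), , drop = FALSE]
      for (k in seq_len(nrow(keys))) {
        sub <- ra[!is.na(ra$locus) & ra$event_id == keys$event_id[k] &
                    ra$locus == keys$locus[k], , drop = FALSE]
        groups <- group_reads(sub)
        if (!nrow(groups)) next
        seqs <- setNames(sub$trimmed_seq, sub$read_id)
        vsc <- setNames(sub$v_score, sub$read_id)
        ids1 <- attr(groups, "read_ids")[[1L]]
        prim <- build_consensus(seqs[ids1], vsc[ids1], config$scoring,
                                config$max_consensus_reads, config$seed)
        cons_rows[[length(cons_rows) + 1L]] <- data.frame(
          consensus_id = paste(keys$event_id[k], keys$locus[k], 1L,
                               sep = "|"),
          event_id = keys$event_id[k], locus = keys$locus[k], rank = 1L,
          sequence = prim$sequence, n_reads = prim$n_reads,
          column_agreement = prim$column_agreement, source = prim$source,
          stringsAsFactors = FALSE)
        sec <- build_secondary(groups, seqs, vsc,
                               config$min_secondary_support, config$scoring,
                               config$max_consensus_reads, config$seed)
        if (!is.null(sec)) {
          cons_rows[[length(cons_rows) + 1L]] <- data.frame(
            consensus_id = paste(keys$event_id[k], keys$locus[k], 2L,
                                 sep = "|"),
            event_id = keys$event_id[k], locus = keys$locus[k], rank = 2L,
            sequence = sec$sequence, n_reads = sec$n_reads,
            column_agreement = sec$column_agreement, source = sec$source,
            stringsAsFactors = FALSE)
        }
      }
      cons <- if (length(cons_rows)) do.call(rbind, cons_rows) else
        empty_table("consensus")
      store_set(store, "consensus", cons)
    })
  } else {
    run_stage("bypass", function() {
      pc <- bypass_demux(config$per_cell_fasta, config$experiment_id)
      sid <- make.unique(pc$sequence_id, sep = "_")
      cons <- data.frame(
        consensus_id = paste0("ext|", sid),
        event_id = pc$event_id,
        locus = ifelse(is.na(pc$locus), "unknown", pc$locus),
        rank = 1L, sequence = pc$sequence, n_reads = 1L,
        column_agreement = 1, source = "external",
        stringsAsFactors = FALSE)
      cons <- cons[order(cons$consensus_id), ]
      store_set(store, "consensus", cons)
    })
  }

  run_stage("consensus_annotation", function() {
    cons <- store_get(store, "consensus")
    seg_rows <- list(); mut_rows <- list(); ann_rows <- list()
    for (i in seq_len(nrow(cons))) {
      ann <- annotate_chain(cons$sequence[i], ref, config$scoring,
                            config$min_scores, config$min_c_len,
                            config$min_c_identity)
      cid <- cons$consensus_id[i]
      asn <- ann$assignment
      locus <- if (!is.na(asn$locus)) asn$locus else cons$locus[i]
      if (cons$source[i] == "external") cons$locus[i] <- locus
      for (st in c("v", "d", "j", "c")) {
        hit <- asn[[st]]
        if (is.null(hit)) next
        al <- hit$alignment
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          consensus_id = cid, segment_type = toupper(st),
          segment_id = hit$segment_id, score = al$score,
          query_start = al$query_start, query_end = al$query_end,
          subject_start = al$subject_start, subject_end = al$subject_end,
          identity = al$identity, cigar = al$cigar,
          stringsAsFactors = FALSE)
      }
      if (nrow(ann$mutations)) {
        m <- ann$mutations
        m$consensus_id <- cid
        mut_rows[[length(mut_rows) + 1L]] <- m
      }
      regions_str <- if (!is.null(ann$regions) && nrow(ann$regions)) {
        paste(sprintf("%s:%d-%d", ann$regions$region, ann$regions$start,
                      ann$regions$end), collapse = ";")
      } else ""
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        consensus_id = cid, event_id = cons$event_id[i], locus = locus,
        rank = cons$rank[i],
        v_call = if (is.null(asn$v)) NA_character_ else asn$v$segment_id,
        d_call = if (is.null(asn$d)) NA_character_ else asn$d$segment_id,
        j_call = if (is.null(asn$j)) NA_character_ else asn$j$segment_id,
        c_call = if (is.null(asn$c)) NA_character_ else asn$c$segment_id,
        junction = ann$junction_nt, junction_aa = ann$junction_aa,
        junction_start = if (is.null(ann$junction)) NA_integer_ else
          ann$junction[["start"]],
        junction_end = if (is.null(ann$junction)) NA_integer_ else
          ann$junction[["end"]],
        isotype = ann$isotype, productive = ann$productive,
        reasons = paste(ann$reasons, collapse = ";"),
        mutation_count = nrow(ann$mutations), regions = regions_str,
        flags = paste(ann$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    store_set(store, "consensus", cons)
    store_set(store, "segment_assignments",
              if (length(seg_rows)) do.call(rbind, seg_rows) else
                empty_table("segment_assignments"))
    store_set(store, "mutations",
              if (length(mut_rows)) do.call(rbind, mut_rows) else
                empty_table("mutations"))
    store_set(store, "chain_annotations",
              if (length(ann_rows)) do.call(rbind, ann_rows) else
                empty_table("chain_annotations"))
  })

  run_stage("link", function() {
    if (!is.null(config$metadata) && !is.null(config$fc) &&
        !is.null(layout)) {
      labels <- data.frame(
        channel = c("kappa_channel", "lambda_channel"),
        reagent = c("anti-Ig-kappa", "anti-Ig-lambda"),
        fluorochrome = c("PE-Cy7", "PE"), stringsAsFactors = FALSE)
      load_metadata_and_fc(store, config$metadata, config$fc, layout,
                           config$experiment_id, labels)
    }
  })

  summary <- NULL
  paths <- c()
  run_stage("export", function() {
    qc <- compute_qc(store, config$contamination_threshold)
    qc_dir <- file.path(config$out_dir, "qc")
    if (config$render_plots) {
      render_qc(qc, qc_dir)
    } else {
      dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(qc$read_length_histogram,
                  file.path(qc_dir, "read_length.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(qc$tag_success, file.path(qc_dir, "tag_success.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(qc$reads_per_well,
                  file.path(qc_dir, "reads_per_well.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })
  if (!stopped) {
    paths <- c(rearrangements = file.path(config$out_dir,
                                          "rearrangements.tsv"),
               cells = file.path(config$out_dir, "cells.tsv"),
               summary = file.path(config$out_dir, "run_summary.json"))
    export_airr(store, paths[["rearrangements"]])
    cells <- export_cells(store, paths[["cells"]])
    summary <- build_run_summary(store, config, cells)
    jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(list(store = store, summary = summary, paths = paths))
}

build_run_summary <- function(store, config, cells) {
  tags <- store_get(store, "tag_assignments")
  cons <- store_get(store, "consensus")
  ann <- store_get(store, "chain_annotations")
  audit <- audit_store(store)
  qc <- compute_qc(store, config$contamination_threshold)
  status_counts <- as.list(setNames(qc$tag_success$count,
                                    qc$tag_success$status))
  param_echo <- config[setdiff(names(config),
                               c("ref", "reads", "scheme", "layout",
                                 "metadata", "fc", "store_path",
                                 "out_dir", "per_cell_fasta"))]
  param_echo$scoring <- unclass(param_echo$scoring)
  list(
    branch = config$branch,
    seed = config$seed,
    parameters = param_echo,
    demux = c(list(reads_in = qc$total_reads,
                   reads_demuxed_total = sum(qc$tag_success$count),
                   reads_assigned_to_wells = sum(!is.na(tags$event_id))),
              status_counts),
    consensus = list(
      n_primary = sum(cons$rank == 1L),
      n_secondary = sum(cons$rank == 2L),
      n_msa = sum(cons$source == "consensus"),
      n_single_read = sum(cons$source == "single_read"),
      n_external = sum(cons$source == "external")),
    annotation = list(
      n_chains = nrow(ann),
      n_productive = sum(ann$productive, na.rm = TRUE),
      n_isotyped = sum(!is.na(ann$isotype))),
    cells = list(
      n_cells = nrow(cells),
      paired_cells = sum(cells$pairing == "paired"),
      heavy_only = sum(cells$pairing == "heavy_only"),
      light_only = sum(cells$pairing == "light_only")),
    qc = list(tag_success_rate = qc$tag_success_rate,
              empty_well_alerts = nrow(qc$empty_well_alerts)),
    audit_ok = isTRUE(attr(audit, "ok"))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; path
#' fields stay paths and are resolved at run time.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}
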