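NONSTOP_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codon_seq <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Deterministic toy germline reference
#'
#' Generates a small synthetic germline reference for testing and
#' simulation: 8 V segments (4 IGHV families, 2 IGKV, 2 IGLV; 300 nt each,
#' free of stop codons in frame 1), 2 IGHD, 4 J (IGHJ1/IGHJ2/IGKJ1/IGLJ1)
#' and 6 constant regions (IGHG1-IGHG4 differing at four subclass-specific
#' positions each, plus IGKC and IGLC1). Every V segment carries a full
#' FR1-FR3 region map. The same seed reproduces the reference byte for
#' byte.
#'
#' @param seed integer RNG seed.
#' @return a [germline_reference()].
#' @export
make_toy_reference <- function(seed = 17L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v_ids <- c("IGHV1-1*01", "IGHV2-1*01", "IGHV3-1*01", "IGHV4-1*01",
             "IGKV1-1*01", "IGKV2-1*01", "IGLV1-1*01", "IGLV2-1*01")
  v_loci <- substr(v_ids, 1L, 3L)
  v_seq <- vapply(v_ids, function(i) random_codon_seq(100L), "")
  d_ids <- c("IGHD1-1*01", "IGHD2-1*01")
  d_seq <- vapply(d_ids, function(i) random_nt(15L), "")
  j_ids <- c("IGHJ1*01", "IGHJ2*01", "IGKJ1*01", "IGLJ1*01")
  j_loci <- substr(j_ids, 1L, 3L)
  j_seq <- vapply(j_ids, function(i) random_codon_seq(16L), "")
  # IgG subclasses share a backbone and differ at 4 dedicated positions each
  g_backbone <- random_codon_seq(34L) # 102 nt
  subclass_pos <- matrix(seq(6L, by = 6L, length.out = 16L), nrow = 4L,
                         byrow = TRUE)
  g_seq <- vapply(1:4, function(k) {
    s <- strsplit(g_backbone, "")[[1L]]
    for (p in subclass_pos[k, ]) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    paste(s, collapse = "")
  }, "")
  c_ids <- c("IGHG1*01", "IGHG2*01", "IGHG3*01", "IGHG4*01",
             "IGKC*01", "IGLC1*01")
  c_loci <- c(rep("IGH", 4L), "IGK", "IGL")
  c_seq <- c(g_seq, random_codon_seq(34L), random_codon_seq(34L))
  segments <- data.frame(
    segment_id = c(v_ids, d_ids, j_ids, c_ids),
    locus = c(v_loci, rep("IGH", 2L), j_loci, c_loci),
    segment_type = c(rep("V", 8L), rep("D", 2L), rep("J", 4L), rep("C", 6L)),
    sequence = c(v_seq, d_seq, j_seq, c_seq),
    stringsAsFactors = FALSE
  )
  region_map <- do.call(rbind, lapply(v_ids, function(sid) {
    data.frame(segment_id = sid,
               region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
               start = c(1L, 76L, 100L, 151L, 175L),
               end = c(75L, 99L, 150L, 174L, 288L),
               stringsAsFactors = FALSE)
  }))
  germline_reference(segments, region_map, organism = "synthetic")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulation parameters for a plated single-cell repertoire
#'
#' Defaults describe a realistic desk-scale matrix PCR experiment: one to
#' three 16x24 plates at 80 percent sort occupancy, a Poisson read depth of
#' 8 reads per chain, per-base substitution error 0.005 (amplicon NGS
#' scale), somatic hypermutation at 1 percent per V base, junction N
#' insertions up to 6 nt per side, and an IgG-subclass isotype mix.
#'
#' @param n_plates,plate_rows,plate_cols plate geometry.
#' @param occupancy fraction of wells containing a sorted cell.
#' @param reads_per_chain_mean Poisson mean reads per chain transcript.
#' @param per_base_error_rate sequencing substitution probability per base.
#' @param indel_rate sequencing indel probability per base (default 0; the
#'   read model is substitution-only unless stress-testing).
#' @param shm_rate per-base somatic hypermutation probability on the V
#'   segment.
#' @param n_junction_max maximum untemplated N nucleotides per junction side.
#' @param isotype_weights named probabilities over heavy constant segments
#'   (must sum to 1).
#' @param kappa_fraction probability a cell uses a kappa (vs lambda) light
#'   chain.
#' @param doublet_rate probability a well carries a second heavy transcript
#'   with a different V-J combination.
#' @param max_read_length reads are truncated to this length (the default
#'   exceeds the toy amplicon length, emulating full-length long reads).
#' @param seed integer RNG seed.
#' @return validated `sim_params` list.
#' @export
sim_params <- function(n_plates = 1L, plate_rows = 16L, plate_cols = 24L,
                       occupancy = 0.8, reads_per_chain_mean = 8,
                       per_base_error_rate = 0.005, indel_rate = 0,
                       shm_rate = 0.01, n_junction_max = 6L,
                       isotype_weights = c(IGHG1 = 0.4, IGHG2 = 0.3,
                                           IGHG3 = 0.2, IGHG4 = 0.1),
                       kappa_fraction = 0.6, doublet_rate = 0,
                       max_read_length = 700L, seed = 1L) {
  stopifnot(n_plates >= 1L, plate_rows >= 1L, plate_cols >= 1L,
            plate_rows <= 26L,
            occupancy >= 0, occupancy <= 1,
            reads_per_chain_mean > 0,
            per_base_error_rate >= 0, per_base_error_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            shm_rate >= 0, shm_rate <= 1,
            n_junction_max >= 0L,
            kappa_fraction >= 0, kappa_fraction <= 1,
            doublet_rate >= 0, doublet_rate <= 1)
  if (abs(sum(isotype_weights) - 1) > 1e-9) {
    stop("isotype_weights must sum to 1")
  }
  structure(list(n_plates = as.integer(n_plates),
                 plate_rows = as.integer(plate_rows),
                 plate_cols = as.integer(plate_cols),
                 occupancy = occupancy,
                 reads_per_chain_mean = reads_per_chain_mean,
                 per_base_error_rate = per_base_error_rate,
                 indel_rate = indel_rate, shm_rate = shm_rate,
                 n_junction_max = as.integer(n_junction_max),
                 isotype_weights = isotype_weights,
                 kappa_fraction = kappa_fraction,
                 doublet_rate = doublet_rate,
                 max_read_length = as.integer(max_read_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a barcode scheme with a guaranteed distance margin
#'
#' Tags are drawn by rejection sampling so that every pair (within and
#' across sides) differs at >= `min_distance` positions, and additionally so
#' that every *shifted* overlap between two distinct tags (shifts up to
#' `max_shift`) differs at >= `shift_min_distance` positions. The first
#' condition makes same-position assignment unambiguous under up to
#' `max_mismatch` errors; the second prevents an errored tag from
#' masquerading as a different tag at a nearby offset, the mechanism that
#' can silently re-address a read to a wrong well.
#'
#' @param n_proximal,n_distal number of tags per side.
#' @param tag_length tag length in nt.
#' @param min_distance minimum pairwise Hamming distance enforced.
#' @param shift_min_distance minimum Hamming distance over the overlapping
#'   bases of every shifted pair of distinct tags.
#' @param max_shift largest relative shift constrained (larger shifts are
#'   protected by the shift's worth of non-tag context bases, which match a
#'   wrong tag only by chance).
#' @param max_mismatch stored on the scheme (see [barcode_scheme()]).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a [barcode_scheme()].
#' @export
make_barcode_scheme <- function(n_proximal, n_distal, tag_length = 12L,
                                min_distance = 5L, shift_min_distance = 4L,
                                max_shift = 2L, max_mismatch = 1L,
                                seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  shift_ok <- function(cand, mat) {
    for (s in seq_len(max_shift)) {
      keep <- tag_length - s
      a <- matrix(cand[(1L + s):tag_length], nrow(mat), keep, byrow = TRUE)
      b <- matrix(cand[1L:keep], nrow(mat), keep, byrow = TRUE)
      if (any(rowSums(mat[, 1L:keep, drop = FALSE] != a) <
                shift_min_distance) ||
          any(rowSums(mat[, (1L + s):tag_length, drop = FALSE] != b) <
                shift_min_distance)) return(FALSE)
    }
    TRUE
  }
  n <- n_proximal + n_distal
  tags <- character(0)
  mat <- NULL
  guard <- 0L
  while (length(tags) < n) {
    guard <- guard + 1L
    if (guard > 1000000L) stop("cannot satisfy tag distance constraint")
    cand <- sample(c("A", "C", "G", "T"), tag_length, replace = TRUE)
    if (is.null(mat) ||
        (all(colSums(t(mat) != cand) >= min_distance) &&
           shift_ok(cand, mat))) {
      mat <- rbind(mat, cand)
      tags <- c(tags, paste(cand, collapse = ""))
    }
  }
  barcode_scheme(
    proximal = setNames(tags[seq_len(n_proximal)],
                        sprintf("P%02d", seq_len(n_proximal))),
    distal = setNames(tags[n_proximal + seq_len(n_distal)],
                      sprintf("D%02d", seq_len(n_distal))),
    max_mismatch = max_mismatch
  )
}

#' Build the matrix layout for a plate set
#'
#' Proximal tags enumerate (plate, row) combinations; distal tags enumerate
#' columns, yielding one unambiguous well per declared tag pair.
#'
#' @param scheme a [barcode_scheme()] with at least `n_plates * plate_rows`
#'   proximal and `plate_cols` distal tags.
#' @param n_plates,plate_rows,plate_cols plate geometry.
#' @return a [plate_layout()].
#' @export
make_plate_layout <- function(scheme, n_plates, plate_rows = 16L,
                              plate_cols = 24L) {
  if (length(scheme$proximal) < n_plates * plate_rows ||
      length(scheme$distal) < plate_cols) {
    stop("barcode scheme too small for plate dimensions")
  }
  grid <- expand.grid(col = seq_len(plate_cols), row = seq_len(plate_rows),
                      plate = seq_len(n_plates))
  plate_layout(data.frame(
    proximal_id = names(scheme$proximal)[(grid$plate - 1L) * plate_rows +
                                           grid$row],
    distal_id = names(scheme$distal)[grid$col],
    plate = grid$plate,
    row = LETTERS[grid$row],
    col = grid$col,
    stringsAsFactors = FALSE
  ))
}

encode_mutations <- function(pos, from, to) {
  if (!length(pos)) return("")
  paste(sprintf("%d:%s>%s", pos, from, to), collapse = ";")
}

#' Decode a compact mutation string
#'
#' Inverse of the `"pos:X>Y;..."` encoding used in truth tables.
#'
#' @param x encoded mutation string (may be `""`).
#' @return data.frame with columns `germline_pos`, `germline_base`,
#'   `query_base`.
#' @export
decode_mutations <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(germline_pos = integer(), germline_base = character(),
                      query_base = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], "[:>]")
  data.frame(germline_pos = as.integer(vapply(parts, `[[`, "", 1L)),
             germline_base = vapply(parts, `[[`, "", 2L),
             query_base = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) {
    return(list(seq = seq, pos = integer(), from = character(),
                to = character()))
  }
  pos <- sort(sample.int(n, k))
  chars <- strsplit(seq, "")[[1L]]
  from <- chars[pos]
  to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
               "")
  chars[pos] <- to
  list(seq = paste(chars, collapse = ""), pos = pos, from = from,
       to = unname(to))
}

apply_read_errors <- function(seq, sub_rate, indel_rate) {
  if (sub_rate > 0) seq <- mutate_seq(seq, sub_rate)$seq
  if (indel_rate > 0) {
    n <- nchar(seq)
    k <- rbinom(1L, n, indel_rate)
    if (k > 0L) {
      chars <- strsplit(seq, "")[[1L]]
      pos <- sort(sample.int(n, k), decreasing = TRUE)
      for (p in pos) {
        if (runif(1L) < 0.5 && length(chars) > 1L) {
          chars <- chars[-p]
        } else {
          chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = p)
        }
      }
      seq <- paste(chars, collapse = "")
    }
  }
  seq
}

recombine_chain <- function(ref, locus, params, exclude_vj = NULL) {
  segs <- ref$segments
  vs <- segs[segs$segment_type == "V" & segs$locus == locus, ]
  js <- segs[segs$segment_type == "J" & segs$locus == locus, ]
  cs <- segs[segs$segment_type == "C" & segs$locus == locus, ]
  repeat {
    v <- vs[sample.int(nrow(vs), 1L), ]
    j <- js[sample.int(nrow(js), 1L), ]
    if (is.null(exclude_vj) ||
        !identical(c(ig_gene(v$segment_id), ig_gene(j$segment_id)),
                   exclude_vj)) break
  }
  if (locus == "IGH") {
    c_id <- sample(names(params$isotype_weights), 1L,
                   prob = params$isotype_weights)
    c_row <- segs[segs$segment_id == paste0(c_id, "*01"), ]
    if (!nrow(c_row)) c_row <- segs[segs$gene == c_id, ][1L, ]
  } else {
    c_row <- cs[sample.int(nrow(cs), 1L), ]
  }
  mut <- mutate_seq(v$sequence, params$shm_rate)
  n1 <- random_nt(sample.int(params$n_junction_max + 1L, 1L) - 1L)
  if (locus == "IGH") {
    ds <- segs[segs$segment_type == "D", ]
    d <- ds[sample.int(nrow(ds), 1L), ]
    dl <- sample.int(4L, 1L) - 1L
    dr <- sample.int(4L, 1L) - 1L
    d_part <- substr(d$sequence, 1L + dl, nchar(d$sequence) - dr)
    n2 <- random_nt(sample.int(params$n_junction_max + 1L, 1L) - 1L)
    insert <- paste0(n1, d_part, n2)
    d_id <- d$segment_id
  } else {
    insert <- n1
    d_id <- NA_character_
  }
  list(v = v$segment_id, d = d_id, j = j$segment_id, c = c_row$segment_id,
       junction_insert = insert,
       mutations = encode_mutations(mut$pos, mut$from, mut$to),
       sequence = paste0(mut$seq, insert, j$sequence, c_row$sequence))
}

#' Simulate a plated single-cell B-cell repertoire with ground truth
#'
#' Emulates the matrix PCR library structure: each occupied well receives one
#' heavy and one light transcript built by V(D)J recombination (uniform
#' segment choice, random N junctions, somatic hypermutation on V, constant
#' region by isotype weight); reads are transcript copies flanked by the
#' well's proximal tag and reverse-complemented distal tag, corrupted by
#' per-base substitution errors. Flow-cytometry index data gives every
#' sorted well a kappa and a lambda channel, with the channel matching the
#' cell's light locus drawn high (log-normal meanlog 9 vs 5, sdlog 0.5).
#' Ground-truth tables record every cell's segments, junction, injected
#' mutations and every read's origin.
#'
#' @param ref a [germline_reference()] (typically [make_toy_reference()]).
#' @param params a [sim_params()].
#' @param experiment_id experiment label used in event ids.
#' @param out_dir optional directory; when given, FASTQ, scheme/layout TSVs,
#'   metadata and FC CSVs and truth TSVs are written there.
#' @return list with `reads` (data.frame read_id, sequence, quality),
#'   `scheme`, `layout`, `fc_index`, `metadata`, `truth` (list `cells`,
#'   `reads`), `params`, `experiment_id` and, when written, `paths`.
#' @export
simulate_repertoire <- function(ref, params, experiment_id = "exp1",
                                out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  scheme <- make_barcode_scheme(params$n_plates * params$plate_rows,
                                params$plate_cols)
  layout <- make_plate_layout(scheme, params$n_plates, params$plate_rows,
                              params$plate_cols)
  wells <- as.data.frame(layout)[, c("plate", "row", "col", "proximal_id",
                                     "distal_id")]
  wells$event_id <- make_event_id(experiment_id, wells$plate, wells$row,
                                  wells$col)
  wells$occupied <- runif(nrow(wells)) < params$occupancy
  if (!any(wells$occupied)) {
    warning("occupancy produced no occupied wells; outputs are empty")
  }

  cells <- list()
  read_rows <- list()
  seqs <- character(0)
  fc <- list()
  for (i in which(wells$occupied)) {
    w <- wells[i, ]
    heavy <- recombine_chain(ref, "IGH", params)
    light_locus <- if (runif(1L) < params$kappa_fraction) "IGK" else "IGL"
    light <- recombine_chain(ref, light_locus, params)
    doublet <- runif(1L) < params$doublet_rate
    heavy2 <- if (doublet) {
      recombine_chain(ref, "IGH", params,
                      exclude_vj = c(ig_gene(heavy$v), ig_gene(heavy$j)))
    } else NULL
    cells[[length(cells) + 1L]] <- data.frame(
      event_id = w$event_id, plate = w$plate, row = w$row, col = w$col,
      heavy_v = heavy$v, heavy_d = heavy$d, heavy_j = heavy$j,
      heavy_c = heavy$c, heavy_junction = heavy$junction_insert,
      heavy_mutations = heavy$mutations, heavy_sequence = heavy$sequence,
      light_locus = light_locus, light_v = light$v, light_j = light$j,
      light_c = light$c, light_junction = light$junction_insert,
      light_mutations = light$mutations, light_sequence = light$sequence,
      is_doublet = doublet,
      heavy2_v = if (doublet) heavy2$v else NA_character_,
      heavy2_j = if (doublet) heavy2$j else NA_character_,
      heavy2_c = if (doublet) heavy2$c else NA_character_,
      heavy2_junction = if (doublet) heavy2$junction_insert else NA_character_,
      heavy2_mutations = if (doublet) heavy2$mutations else NA_character_,
      heavy2_sequence = if (doublet) heavy2$sequence else NA_character_,
      stringsAsFactors = FALSE
    )
    ptag <- scheme$proximal[[w$proximal_id]]
    dtag_rc <- revcomp(scheme$distal[[w$distal_id]])
    transcripts <- list(list(seq = heavy$sequence, locus = "IGH", no = 1L),
                        list(seq = light$sequence, locus = light_locus,
                             no = 1L))
    if (doublet) {
      transcripts <- c(transcripts,
                       list(list(seq = heavy2$sequence, locus = "IGH",
                                 no = 2L)))
    }
    for (tr in transcripts) {
      n_reads <- rpois(1L, params$reads_per_chain_mean)
      if (n_reads == 0L) next
      amplicon <- paste0(ptag, tr$seq, dtag_rc)
      amplicon <- substr(amplicon, 1L, params$max_read_length)
      for (r in seq_len(n_reads)) {
        seqs <- c(seqs, apply_read_errors(amplicon,
                                          params$per_base_error_rate,
                                          params$indel_rate))
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          event_id = w$event_id, locus = tr$locus, transcript_no = tr$no,
          proximal_tag = w$proximal_id, distal_tag = w$distal_id,
          stringsAsFactors = FALSE
        )
      }
    }
    hi <- rlnorm(1L, meanlog = 9, sdlog = 0.5)
    lo <- rlnorm(1L, meanlog = 5, sdlog = 0.5)
    fc[[length(fc) + 1L]] <- data.frame(
      plate = w$plate, row = w$row, col = w$col,
      kappa_channel = if (light_locus == "IGK") hi else lo,
      lambda_channel = if (light_locus == "IGL") hi else lo,
      stringsAsFactors = FALSE
    )
  }
  truth_cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(event_id = character(), stringsAsFactors = FALSE)
  truth_reads <- if (length(read_rows)) do.call(rbind, read_rows) else
    data.frame(event_id = character(), locus = character(),
               transcript_no = integer(), proximal_tag = character(),
               distal_tag = character(), stringsAsFactors = FALSE)
  if (nrow(truth_reads)) {
    truth_reads$read_id <- sprintf("r%06d", seq_len(nrow(truth_reads)))
    truth_reads <- truth_reads[, c("read_id", "event_id", "locus",
                                   "transcript_no", "proximal_tag",
                                   "distal_tag")]
  } else {
    truth_reads$read_id <- character(0)
  }
  reads <- data.frame(read_id = truth_reads$read_id, sequence = seqs,
                      quality = strrep("?", nchar(seqs)), # constant Q30
                      stringsAsFactors = FALSE)
  fc_index <- if (length(fc)) do.call(rbind, fc) else
    data.frame(plate = integer(), row = character(), col = integer(),
               kappa_channel = numeric(), lambda_channel = numeric())
  metadata <- data.frame(
    plate = wells$plate, row = wells$row, col = wells$col,
    donor = sprintf("donor%d", wells$plate),
    sample = sprintf("sample%d", wells$plate),
    sort_date = "2026-01-15",
    empty_well = !wells$occupied,
    stringsAsFactors = FALSE
  )
  out <- list(reads = reads, scheme = scheme, layout = layout,
              fc_index = fc_index, metadata = metadata,
              truth = list(cells = truth_cells, reads = truth_reads),
              params = params, experiment_id = experiment_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      reads = file.path(out_dir, "reads.fastq"),
      scheme = file.path(out_dir, "scheme.tsv"),
      layout = file.path(out_dir, "layout.tsv"),
      fc_index = file.path(out_dir, "fc_index.csv"),
      metadata = file.path(out_dir, "metadata.csv"),
      truth_cells = file.path(out_dir, "truth_cells.tsv"),
      truth_reads = file.path(out_dir, "truth_reads.tsv")
    )
    write_fastq(reads, paths[["reads"]])
    write_barcode_scheme(scheme, paths[["scheme"]])
    write_plate_layout(layout, paths[["layout"]])
    write.csv(fc_index, paths[["fc_index"]], row.names = FALSE, quote = FALSE)
    write.csv(metadata, paths[["metadata"]], row.names = FALSE, quote = FALSE)
    write.table(truth_cells, paths[["truth_cells"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth_reads, paths[["truth_reads"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Read / write FASTQ as a plain data.frame
#'
#' Thin wrappers over Biostrings for the pipeline's read table
#' representation (columns `read_id`, `sequence`, `quality`).
#'
#' @param path FASTQ path.
#' @return [read_fastq()]: data.frame with read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  df <- data.frame(read_id = sub("\\s.*$", "", names(set)),
                   sequence = unname(as.character(set)),
                   quality = unname(as.character(
                     S4Vectors::mcols(set)$qualities)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' @rdname read_fastq
#' @param reads data.frame with read_id, sequence and quality columns.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads)) {
    idx <- seq_len(nrow(reads))
    lines[4L * idx - 3L] <- paste0("@", reads$read_id)
    lines[4L * idx - 2L] <- reads$sequence
    lines[4L * idx - 1L] <- "+"
    lines[4L * idx] <- reads$quality
  }
  writeLines(lines, path)
  invisible(path)
}
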