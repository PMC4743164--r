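#' Barcode scheme for two-dimensional well demultiplexing
#'
#' In the matrix PCR protocol every amplicon carries a proximal tag at the 5'
#' end and a distal tag at the 3' end (as reverse complement); the tag pair
#' encodes the microtiter-plate well of the sorted cell. Tags are matched by
#' Hamming distance inside fixed windows at the read ends. The scheme is
#' valid only if, within each tag set, the minimum pairwise Hamming distance
#' exceeds `2 * max_mismatch`, which guarantees that a read with at most
#' `max_mismatch` errors per tag can never be assigned to a wrong tag.
#'
#' @param proximal,distal named character vectors (tag_id -> sequence). All
#'   tags within one set must share one length.
#' @param proximal_window,distal_window number of bases searched from the 5'
#'   and 3' read end respectively.
#' @param max_mismatch maximum Hamming mismatches for an accepted tag hit.
#' @return a `barcode_scheme` object.
#' @export
barcode_scheme <- function(proximal, distal, proximal_window = 25L,
                           distal_window = 25L, max_mismatch = 1L) {
  check_tag_set <- function(tags, side) {
    if (is.null(names(tags)) || any(!nzchar(names(tags)))) {
      stop(side, " tags must be named by tag_id")
    }
    if (length(unique(nchar(tags))) != 1L) {
      stop(side, " tags must all have the same length")
    }
    if (length(tags) > 1L) {
      mind <- min_pairwise_hamming(tags)
      if (mind <= 2L * max_mismatch) {
        stop(side, " tag set violates the distance invariant: minimum ",
             "pairwise Hamming distance ", mind, " is not > 2*max_mismatch (",
             2L * max_mismatch, ")")
      }
    }
    tags
  }
  structure(list(proximal = check_tag_set(proximal, "proximal"),
                 distal = check_tag_set(distal, "distal"),
                 proximal_window = as.integer(proximal_window),
                 distal_window = as.integer(distal_window),
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_scheme")
}

min_pairwise_hamming <- function(tags) {
  mat <- do.call(rbind, strsplit(unname(tags), ""))
  n <- nrow(mat)
  best <- ncol(mat)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      best <- min(best, sum(mat[i, ] != mat[j, ]))
    }
  }
  best
}

#' Read / write a barcode scheme as TSV
#'
#' TSV columns: `tag_id`, `side` (`proximal`/`distal`), `sequence`.
#'
#' @param path TSV path.
#' @param ... passed through to [barcode_scheme()] (windows, max_mismatch).
#' @return [read_barcode_scheme()]: a `barcode_scheme`.
#' @export
read_barcode_scheme <- function(path, ...) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  barcode_scheme(
    proximal = setNames(df$sequence[df$side == "proximal"],
                        df$tag_id[df$side == "proximal"]),
    distal = setNames(df$sequence[df$side == "distal"],
                      df$tag_id[df$side == "distal"]),
    ...
  )
}

#' @rdname read_barcode_scheme
#' @param scheme a `barcode_scheme`.
#' @export
write_barcode_scheme <- function(scheme, path) {
  df <- rbind(
    data.frame(tag_id = names(scheme$proximal), side = "proximal",
               sequence = unname(scheme$proximal), stringsAsFactors = FALSE),
    data.frame(tag_id = names(scheme$distal), side = "distal",
               sequence = unname(scheme$distal), stringsAsFactors = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plate layout: map tag pairs to wells
#'
#' A layout maps each declared (proximal_id, distal_id) pair to exactly one
#' well (plate, row, col). TSV columns: `proximal_id`, `distal_id`, `plate`,
#' `row`, `col`.
#'
#' @param df data.frame with the five layout columns.
#' @return validated layout data.frame (class `plate_layout`).
#' @export
plate_layout <- function(df) {
  need <- c("proximal_id", "distal_id", "plate", "row", "col")
  if (!all(need %in% names(df))) {
    stop("layout must have columns ", paste(need, collapse = ", "))
  }
  df$plate <- as.integer(df$plate)
  df$col <- as.integer(df$col)
  df$row <- as.character(df$row)
  if (any(df$plate < 1L) || any(df$col < 1L)) stop("plate and col must be >= 1")
  key <- paste(df$proximal_id, df$distal_id, sep = "\r")
  if (anyDuplicated(key)) stop("layout maps a tag pair to more than one well")
  well <- paste(df$plate, df$row, df$col, sep = "\r")
  if (anyDuplicated(well)) stop("layout assigns a well to more than one tag pair")
  df <- df[, need]
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' @rdname plate_layout
#' @param path TSV path.
#' @export
read_plate_layout <- function(path) {
  plate_layout(read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(row = "character")))
}

#' @rdname plate_layout
#' @param layout a `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  write.table(as.data.frame(layout), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Canonical event identifier of a sorted cell
#'
#' @param experiment_id experiment label.
#' @param plate plate number (>= 1).
#' @param row row label (letter).
#' @param col column number (>= 1).
#' @return character vector like `"exp1_p01A03"`.
#' @export
make_event_id <- function(experiment_id, plate, row, col) {
  sprintf("%s_p%02d%s%02d", experiment_id, as.integer(plate), row,
          as.integer(col))
}

#' Identify proximal and distal tags in reads
#'
#' Proximal tags are searched as-is within the first `proximal_window` bases;
#' distal tags are searched as reverse complements within the last
#' `distal_window` bases (reads are assumed in amplicon orientation).
#' Because the amplicon places each tag directly at its read end, offsets
#' are scanned outward from that end and the first offset holding a tag
#' within `max_mismatch` wins, with the fewest mismatches at that offset;
#' this keeps chance tag-like sequence deeper in the window from
#' outcompeting a slightly errored true tag (the mechanism behind
#' cross-well misassignment). If two distinct tags tie at the winning
#' offset the side is ambiguous and never force-resolved.
#'
#' @param reads data.frame with columns `read_id` and `sequence`.
#' @param scheme a [barcode_scheme()].
#' @return data.frame, one row per read: `read_id`, `proximal_tag`,
#'   `proximal_offset`, `proximal_mismatches`, `distal_tag`, `distal_offset`,
#'   `distal_mismatches`, `status` (one of `both`, `proximal_only`,
#'   `distal_only`, `none`, `ambiguous`). Offsets are 1-based positions of
#'   the tag match on the read.
#' @export
identify_tags <- function(reads, scheme) {
  n <- nrow(reads)
  seqs <- toupper(reads$sequence)
  lens <- nchar(seqs)
  ptags <- scheme$proximal
  dtags_rc <- revcomp(scheme$distal)
  plen <- nchar(ptags[[1L]])
  dlen <- nchar(scheme$distal[[1L]])

  pwin <- substr(seqs, 1L, pmin(lens, scheme$proximal_window))
  dstart <- pmax(1L, lens - scheme$distal_window + 1L)
  dwin <- substr(seqs, dstart, lens)

  phit <- .tag_scan_dir_cpp(pwin, unname(ptags), scheme$max_mismatch, FALSE)
  dhit <- .tag_scan_dir_cpp(dwin, unname(dtags_rc), scheme$max_mismatch, TRUE)

  side_result <- function(hit, tag_names, taglen, offset_base) {
    ok <- !is.na(hit$mismatches) & hit$mismatches <= scheme$max_mismatch
    amb <- ok & hit$tie
    list(tag = ifelse(ok & !amb, tag_names[hit$tag_index], NA_character_),
         offset = ifelse(ok & !amb, offset_base + hit$offset, NA_integer_),
         mismatches = ifelse(ok & !amb, hit$mismatches, NA_integer_),
         accepted = ok & !amb, ambiguous = amb)
  }
  p <- side_result(phit, names(ptags), plen, rep(1L, n))
  d <- side_result(dhit, names(scheme$distal), dlen, dstart)

  status <- rep("none", n)
  status[p$accepted & d$accepted] <- "both"
  status[p$accepted & !d$accepted & !d$ambiguous] <- "proximal_only"
  status[!p$accepted & !p$ambiguous & d$accepted] <- "distal_only"
  status[p$ambiguous | d$ambiguous] <- "ambiguous"

  data.frame(read_id = reads$read_id,
             proximal_tag = p$tag, proximal_offset = p$offset,
             proximal_mismatches = p$mismatches,
             distal_tag = d$tag, distal_offset = d$offset,
             distal_mismatches = d$mismatches,
             status = status, stringsAsFactors = FALSE)
}

#' Decode tag assignments to single-cell event identifiers
#'
#' Reads with status `both` whose (proximal, distal) tag pair is declared in
#' the layout receive the mapped well's event id; every other read is
#' unassigned with its reason recorded (`status` for incomplete tag pairs,
#' `unmapped_pair` for pairs absent from the layout).
#'
#' @param tags output of [identify_tags()].
#' @param layout a [plate_layout()].
#' @param experiment_id experiment label used in event ids.
#' @return `tags` with columns `event_id`, `plate`, `row`, `col`,
#'   `unassigned_reason` appended (`NA` event for unassigned reads).
#' @export
decode_events <- function(tags, layout, experiment_id = "exp1") {
  key <- paste(tags$proximal_tag, tags$distal_tag, sep = "\r")
  lkey <- paste(layout$proximal_id, layout$distal_id, sep = "\r")
  idx <- match(key, lkey)
  both <- tags$status == "both"
  hit <- both & !is.na(idx)
  out <- tags
  out$plate <- ifelse(hit, layout$plate[idx], NA_integer_)
  out$row <- ifelse(hit, layout$row[idx], NA_character_)
  out$col <- ifelse(hit, layout$col[idx], NA_integer_)
  out$event_id <- NA_character_
  out$event_id[hit] <- make_event_id(experiment_id, out$plate[hit],
                                     out$row[hit], out$col[hit])
  out$unassigned_reason <- NA_character_
  out$unassigned_reason[!both] <- tags$status[!both]
  out$unassigned_reason[both & is.na(idx)] <- "unmapped_pair"
  out
}

#' Ingest pre-demultiplexed single-cell sequences (Sanger-style input)
#'
#' For data already at single-cell level, tag identification and consensus
#' building are skipped: each FASTA record enters the pipeline as a finished
#' per-cell sequence. Headers follow the pipe dialect
#' `sequence_id|plate|row|col` with an optional fifth `locus` field, e.g.
#' `>c1|1|A|1|IGH`. Malformed headers are skipped with a warning and
#' counted.
#'
#' @param fasta_path path to the per-cell FASTA.
#' @param experiment_id experiment label used in event ids.
#' @return data.frame: `sequence_id`, `event_id`, `plate`, `row`, `col`,
#'   `locus` (NA when absent), `sequence`; attribute `n_skipped` counts
#'   records dropped for malformed headers.
#' @export
bypass_demux <- function(fasta_path, experiment_id = "exp1") {
  set <- Biostrings::readDNAStringSet(fasta_path)
  fields <- strsplit(names(set), "|", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  plate <- suppressWarnings(
    as.integer(vapply(fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_, ""))
  )
  col <- suppressWarnings(
    as.integer(vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, ""))
  )
  ok <- nf >= 4L & !is.na(plate) & !is.na(col)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) with malformed per-cell headers skipped")
  }
  f <- fields[ok]
  out <- data.frame(
    sequence_id = vapply(f, `[[`, "", 1L),
    plate = plate[ok],
    row = vapply(f, `[[`, "", 3L),
    col = col[ok],
    locus = vapply(f, function(x) if (length(x) >= 5L) x[5L] else NA_character_, ""),
    sequence = as.character(set)[ok],
    stringsAsFactors = FALSE
  )
  out$event_id <- make_event_id(experiment_id, out$plate, out$row, out$col)
  out <- out[, c("sequence_id", "event_id", "plate", "row", "col", "locus",
                 "sequence")]
  attr(out, "n_skipped") <- n_skipped
  out
}
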