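#' Germline gene and family name derivation
#'
#' IMGT-style segment identifiers are hierarchical: an allele id such as
#' `IGHV1-1*01` names gene `IGHV1-1` within family `IGHV1`. `ig_gene()`
#' strips the allele suffix (`*NN`); `ig_family()` additionally strips the
#' gene-number suffix (`-N`). Both are total and idempotent on already
#' stripped names.
#'
#' @param segment_id character vector of segment, gene or family identifiers.
#' @return character vector of the same length.
#' @examples
#' ig_gene("IGHV1-1*01")   # "IGHV1-1"
#' ig_family("IGHV1-1*01") # "IGHV1"
#' @export
ig_gene <- function(segment_id) {
  sub("\\*.*$", "", segment_id)
}

#' @rdname ig_gene
#' @export
ig_family <- function(segment_id) {
  sub("-.*$", "", ig_gene(segment_id))
}

ALLOWED_LOCI <- c("IGH", "IGK", "IGL")
ALLOWED_SEGMENT_TYPES <- c("V", "D", "J", "C")
V_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")

parse_reference_fasta <- function(path, expected_type) {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  bad <- vapply(fields, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed reference FASTA header(s) in ", path, ": ",
         paste(headers[bad], collapse = ", "),
         " (expected 'segment_id|locus|segment_type')")
  }
  df <- data.frame(
    segment_id = vapply(fields, `[[`, "", 1L),
    locus = vapply(fields, `[[`, "", 2L),
    segment_type = vapply(fields, `[[`, "", 3L),
    sequence = as.character(set),
    stringsAsFactors = FALSE
  )
  if (any(!df$locus %in% ALLOWED_LOCI)) {
    stop("unknown locus code in ", path, ": ",
         paste(unique(setdiff(df$locus, ALLOWED_LOCI)), collapse = ", "))
  }
  if (any(df$segment_type != expected_type)) {
    stop("segment_type mismatch in ", path, ": expected ", expected_type)
  }
  if (any(df$sequence == "" | grepl("[^ACGT]", df$sequence))) {
    stop("reference sequences must be non-empty and over {A,C,G,T} (", path, ")")
  }
  df
}

#' Load a germline reference
#'
#' Reads germline V, D, J and constant-region segments from four FASTA files
#' plus a per-V-segment region map (TSV with columns `segment_id`, `region`,
#' `start`, `end`; 1-based inclusive coordinates on the germline segment).
#' FASTA headers follow the pipe dialect `segment_id|locus|segment_type`,
#' e.g. `IGHV1-1*01|IGH|V`. Gene and family names are derived with
#' [ig_gene()] and [ig_family()].
#'
#' @param v_fasta,d_fasta,j_fasta,c_fasta paths to the segment FASTA files.
#'   `d_fasta` may be `NULL` for references without D segments.
#' @param region_map_tsv path to the FR/CDR region map TSV, or `NULL`.
#' @param organism label stored with the reference.
#' @return a `germline_reference` object: list with `segments` (data.frame:
#'   segment_id, gene, family, locus, segment_type, sequence), `region_map`
#'   (data.frame: segment_id, region, start, end) and `organism`.
#' @export
load_reference <- function(v_fasta, d_fasta, j_fasta, c_fasta,
                           region_map_tsv = NULL, organism = "unspecified") {
  parts <- list(parse_reference_fasta(v_fasta, "V"))
  if (!is.null(d_fasta)) parts <- c(parts, list(parse_reference_fasta(d_fasta, "D")))
  parts <- c(parts,
             list(parse_reference_fasta(j_fasta, "J")),
             list(parse_reference_fasta(c_fasta, "C")))
  segments <- do.call(rbind, parts)
  region_map <- if (is.null(region_map_tsv)) {
    data.frame(segment_id = character(), region = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  } else {
    rm <- read.delim(region_map_tsv, stringsAsFactors = FALSE)
    rm$start <- as.integer(rm$start)
    rm$end <- as.integer(rm$end)
    rm
  }
  germline_reference(segments, region_map, organism)
}

#' Construct and validate a germline reference from in-memory tables
#'
#' @param segments data.frame with columns segment_id, locus, segment_type,
#'   sequence (gene/family columns are derived and overwritten).
#' @param region_map data.frame with columns segment_id, region, start, end.
#' @param organism label stored with the reference.
#' @return a validated `germline_reference`.
#' @export
germline_reference <- function(segments, region_map = NULL,
                               organism = "unspecified") {
  if (is.null(region_map)) {
    region_map <- data.frame(segment_id = character(), region = character(),
                             start = integer(), end = integer(),
                             stringsAsFactors = FALSE)
  }
  segments$gene <- ig_gene(segments$segment_id)
  segments$family <- ig_family(segments$segment_id)
  segments <- segments[, c("segment_id", "gene", "family", "locus",
                           "segment_type", "sequence")]
  rownames(segments) <- NULL
  dup <- segments$segment_id[duplicated(segments$segment_id)]
  if (length(dup)) {
    stop("duplicate segment_id in reference: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!segments$locus %in% ALLOWED_LOCI)) stop("unknown locus code")
  if (any(!segments$segment_type %in% ALLOWED_SEGMENT_TYPES)) {
    stop("unknown segment_type")
  }
  if (any(segments$sequence == "" | grepl("[^ACGT]", segments$sequence))) {
    stop("reference sequences must be non-empty and over {A,C,G,T}")
  }
  v_loci <- unique(segments$locus[segments$segment_type == "V"])
  j_loci <- unique(segments$locus[segments$segment_type == "J"])
  missing_j <- setdiff(v_loci, j_loci)
  if (length(missing_j)) {
    stop("locus with V but no J segment: ", paste(missing_j, collapse = ", "))
  }
  validate_region_map(region_map, segments)
  obj <- list(segments = segments, region_map = region_map,
              organism = organism)
  class(obj) <- "germline_reference"
  obj
}

validate_region_map <- function(region_map, segments) {
  if (!nrow(region_map)) return(invisible(TRUE))
  need <- c("segment_id", "region", "start", "end")
  if (!all(need %in% names(region_map))) {
    stop("region map must have columns ", paste(need, collapse = ", "))
  }
  v_ids <- segments$segment_id[segments$segment_type == "V"]
  unknown <- setdiff(region_map$segment_id, v_ids)
  if (length(unknown)) {
    stop("region map references non-V or unknown segment_id: ",
         paste(unknown, collapse = ", "))
  }
  if (any(!region_map$region %in% V_REGIONS)) {
    stop("region names must be among ", paste(V_REGIONS, collapse = ", "))
  }
  seg_len <- setNames(nchar(segments$sequence), segments$segment_id)
  for (sid in unique(region_map$segment_id)) {
    rows <- region_map[region_map$segment_id == sid, ]
    rows <- rows[match(V_REGIONS[V_REGIONS %in% rows$region], rows$region), ]
    if (any(rows$start < 1L) || any(rows$end > seg_len[[sid]])) {
      stop("region interval outside segment ", sid)
    }
    if (any(rows$start > rows$end)) stop("empty region interval in ", sid)
    if (nrow(rows) > 1L &&
        any(rows$start[-1L] <= rows$end[-nrow(rows)])) {
      stop("region intervals overlap or are out of order in ", sid)
    }
  }
  invisible(TRUE)
}

#' @export
print.germline_reference <- function(x, ...) {
  tab <- table(x$segments$segment_type)
  cat("germline_reference (", x$organism, "): ",
      nrow(x$segments), " segments [",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      "]; region maps for ", length(unique(x$region_map$segment_id)),
      " V segments\n", sep = "")
  invisible(x)
}

#' Look up one germline segment
#'
#' @param ref a `germline_reference`.
#' @param segment_id segment identifier.
#' @return one-row data.frame from `ref$segments`.
#' @export
ref_segment <- function(ref, segment_id) {
  row <- ref$segments[ref$segments$segment_id == segment_id, ]
  if (!nrow(row)) stop("unknown segment_id: ", segment_id)
  row
}

region_map_for <- function(ref, segment_id) {
  rm <- ref$region_map[ref$region_map$segment_id == segment_id, , drop = FALSE]
  rm[order(match(rm$region, V_REGIONS)), , drop = FALSE]
}

#' Write a germline reference back to FASTA + region-map TSV
#'
#' Inverse of [load_reference()]: emits `v.fasta`, `d.fasta` (when D segments
#' exist), `j.fasta`, `c.fasta` and `regions.tsv` under `dir`.
#'
#' @param ref a `germline_reference`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (st in ALLOWED_SEGMENT_TYPES) {
    seg <- ref$segments[ref$segments$segment_type == st, ]
    if (!nrow(seg) && st == "D") next
    set <- Biostrings::DNAStringSet(seg$sequence)
    names(set) <- paste(seg$segment_id, seg$locus, seg$segment_type, sep = "|")
    p <- file.path(dir, paste0(tolower(st), ".fasta"))
    Biostrings::writeXStringSet(set, p)
    paths[st] <- p
  }
  rp <- file.path(dir, "regions.tsv")
  write.table(ref$region_map, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["regions"] <- rp
  invisible(paths)
}
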