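#' Compute quality-control metrics for a high-throughput run
#'
#' Four metrics over the stored reads and tag assignments: the read-length
#' histogram (bins of `length_binwidth` nt), tag-identification success
#' (counts per assignment status and the rate of fully tagged reads), the
#' distribution of demultiplexed reads per well (including zero counts for
#' sorted wells that received none), and cross-contamination alerts for
#' metadata-flagged empty wells that nevertheless received at least
#' `contamination_threshold` assigned reads.
#'
#' @param store an `ig_store` with demultiplexing results loaded.
#' @param contamination_threshold minimum assigned reads in a declared-empty
#'   well that triggers an alert.
#' @param length_binwidth width of the read-length histogram bins (nt).
#' @return a `qc_report` list: `read_length_histogram` (data.frame
#'   `length_bin`, `count`; bin label = lower bound), `tag_success`
#'   (data.frame `status`, `count`), `tag_success_rate`, `reads_per_well`
#'   (data.frame `event_id`, `count`), `empty_well_alerts` (data.frame
#'   `event_id`, `read_count`), `total_reads`.
#' @export
compute_qc <- function(store, contamination_threshold = 5L,
                       length_binwidth = 10L) {
  reads <- store_get(store, "reads")
  tags <- store_get(store, "tag_assignments")
  se <- store_get(store, "sort_events")
  total <- nrow(reads)

  lens <- nchar(reads$sequence)
  bins <- (lens %/% length_binwidth) * length_binwidth
  hist_tab <- table(bins)
  read_length_histogram <- data.frame(
    length_bin = as.integer(names(hist_tab)),
    count = as.integer(hist_tab), stringsAsFactors = FALSE)

  statuses <- c("both", "proximal_only", "distal_only", "none", "ambiguous")
  scounts <- vapply(statuses, function(s) sum(tags$status == s), 1L)
  tag_success <- data.frame(status = statuses, count = unname(scounts),
                            stringsAsFactors = FALSE)
  rate <- if (nrow(tags)) unname(scounts[["both"]]) / nrow(tags) else 0

  assigned <- tags[!is.na(tags$event_id), , drop = FALSE]
  well_ids <- if (nrow(se)) se$event_id else sort(unique(assigned$event_id))
  counts <- vapply(well_ids, function(ev) sum(assigned$event_id == ev), 1L)
  reads_per_well <- data.frame(event_id = well_ids, count = unname(counts),
                               stringsAsFactors = FALSE)
  reads_per_well <- reads_per_well[order(reads_per_well$event_id), ]
  rownames(reads_per_well) <- NULL

  alerts <- data.frame(event_id = character(), read_count = integer(),
                       stringsAsFactors = FALSE)
  if (nrow(se)) {
    empty_ids <- se$event_id[se$empty_well]
    rc <- reads_per_well$count[match(empty_ids, reads_per_well$event_id)]
    rc[is.na(rc)] <- 0L
    bad <- rc >= contamination_threshold
    alerts <- data.frame(event_id = empty_ids[bad], read_count = rc[bad],
                         stringsAsFactors = FALSE)
  }
  structure(list(read_length_histogram = read_length_histogram,
                 tag_success = tag_success, tag_success_rate = rate,
                 reads_per_well = reads_per_well,
                 empty_well_alerts = alerts, total_reads = total),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d reads; tag success %.1f%%; %d wells; ",
                     "%d empty-well alert(s)\n"),
              x$total_reads, 100 * x$tag_success_rate,
              nrow(x$reads_per_well), nrow(x$empty_well_alerts)))
  invisible(x)
}

open_device <- function(path, width = 7, height = 5) {
  if (grepl("\\.pdf$", path)) grDevices::pdf(path, width = width,
                                             height = height)
  else grDevices::png(path, width = width * 120, height = height * 120)
}

#' Render the QC report as plots with machine-readable TSV twins
#'
#' Writes one plot per metric (read-length distribution, tag status counts,
#' reads-per-well distribution) and, for each, a TSV holding exactly the
#' plotted series; the TSVs are byte-stable across re-renders of the same
#' report.
#'
#' @param report a [compute_qc()] result.
#' @param out_dir output directory (created if absent).
#' @param device `"png"` or `"pdf"`.
#' @return invisibly, character vector of written paths.
#' @export
render_qc <- function(report, out_dir, device = c("png", "pdf")) {
  device <- match.arg(device)
  if (device == "png" && !capabilities("png")) device <- "pdf"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(stem, df, plot_fun) {
    tsv <- file.path(out_dir, paste0(stem, ".tsv"))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    img <- file.path(out_dir, paste0(stem, ".", device))
    open_device(img)
    plot_fun()
    grDevices::dev.off()
    paths <<- c(paths, tsv, img)
  }
  emit("read_length", report$read_length_histogram, function() {
    h <- report$read_length_histogram
    graphics::barplot(h$count, names.arg = h$length_bin,
                      xlab = "read length (nt, bin lower bound)",
                      ylab = "reads", main = "Read length distribution",
                      col = "steelblue", border = NA, las = 2)
  })
  emit("tag_success", report$tag_success, function() {
    t <- report$tag_success
    graphics::barplot(t$count, names.arg = t$status,
                      xlab = "tag status", ylab = "reads",
                      main = sprintf("Tag identification (%.1f%% both)",
                                     100 * report$tag_success_rate),
                      col = "darkseagreen", border = NA)
  })
  emit("reads_per_well", report$reads_per_well, function() {
    graphics::hist(report$reads_per_well$count,
                   breaks = seq(-0.5, max(report$reads_per_well$count, 1) +
                                  0.5, by = 1),
                   xlab = "reads per well", ylab = "wells",
                   main = "Reads per well", col = "lightsalmon",
                   border = "white")
  })
  invisible(paths)
}
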