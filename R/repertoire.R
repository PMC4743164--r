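level_columns <- function(level) {
  switch(level,
         V_family = c("heavy_v_family", "light_v_family"),
         J_family = c("heavy_j_family", "light_j_family"),
         V_gene = c("heavy_v_gene", "light_v_gene"),
         J_gene = c("heavy_j_gene", "light_j_gene"),
         stop("unknown level: ", level))
}

#' Heavy:light segment association matrices
#'
#' For paired cells, counts how often each heavy V (or J) segment family (or
#' gene) co-occurs with each light family/gene and normalizes the counts to
#' relative association frequencies. One matrix per stratum (e.g. per
#' donor); unpaired cells are excluded and counted. By default frequencies
#' are normalized over the whole matrix so they sum to 1 per stratum;
#' `normalize = "row"` normalizes each heavy-segment row instead.
#'
#' @param cells cell records from [query_cells()].
#' @param level one of `"V_family"`, `"J_family"`, `"V_gene"`, `"J_gene"`.
#' @param stratify_by optional cell-record column (e.g. `"donor"`); `NULL`
#'   builds one global matrix.
#' @param normalize `"matrix"` (default) or `"row"`.
#' @return list of `pairing_matrix` objects: `counts` (integer matrix, heavy
#'   rows x light columns), `frequencies`, `level`, `stratum`, `n_paired`,
#'   `n_excluded`. Strata with zero paired cells are omitted with a warning.
#' @export
pairing_matrix <- function(cells, level = "V_family", stratify_by = NULL,
                           normalize = c("matrix", "row")) {
  normalize <- match.arg(normalize)
  cols <- level_columns(level)
  paired <- cells[cells$pairing == "paired" & !is.na(cells[[cols[1L]]]) &
                    !is.na(cells[[cols[2L]]]), , drop = FALSE]
  n_excluded <- nrow(cells) - nrow(paired)
  strata <- if (is.null(stratify_by)) list(all = paired) else
    split(paired, paired[[stratify_by]])
  out <- list()
  for (sname in names(strata)) {
    sub <- strata[[sname]]
    if (!nrow(sub)) {
      warning("stratum '", sname, "' has zero paired cells; matrix omitted")
      next
    }
    counts <- table(heavy = sub[[cols[1L]]], light = sub[[cols[2L]]])
    counts <- unclass(counts)
    freqs <- if (normalize == "matrix") counts / sum(counts) else
      sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
    stopifnot(all(counts >= 0), sum(counts) == nrow(sub))
    if (normalize == "matrix") stopifnot(abs(sum(freqs) - 1) < 1e-9)
    out[[sname]] <- structure(
      list(counts = counts, frequencies = freqs, level = level,
           stratum = sname, n_paired = nrow(sub), n_excluded = n_excluded),
      class = "pairing_matrix")
  }
  out
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat(sprintf("pairing_matrix %s stratum=%s: %d paired cells\n", x$level,
              x$stratum, x$n_paired))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Isotype distribution split by light-chain locus
#'
#' For cells with both a heavy and a light chain, tabulates the heavy-chain
#' isotype within each (stratum, light locus) combination; cells without an
#' assigned isotype fall into category `"unassigned"`. Both the kappa and
#' lambda stratum are emitted even when empty.
#'
#' @param cells cell records from [query_cells()].
#' @param stratify_by cell-record column defining strata (default
#'   `"donor"`); `NULL` pools everything.
#' @return list of `isotype_distribution` objects: `stratum`, `light_locus`,
#'   `counts` (named integer vector), `total`.
#' @export
isotype_by_light_locus <- function(cells, stratify_by = "donor") {
  paired <- cells[cells$pairing == "paired", , drop = FALSE]
  paired$isotype[is.na(paired$isotype)] <- "unassigned"
  strata <- if (is.null(stratify_by)) list(all = paired) else
    split(paired, paired[[stratify_by]])
  out <- list()
  for (sname in names(strata)) {
    for (locus in c("IGK", "IGL")) {
      sub <- strata[[sname]][strata[[sname]]$light_locus == locus, ,
                             drop = FALSE]
      counts <- if (nrow(sub)) {
        tab <- table(sub$isotype)
        setNames(as.integer(tab), names(tab))
      } else integer(0)
      stopifnot(sum(counts) == nrow(sub))
      out[[paste(sname, locus, sep = ".")]] <- structure(
        list(stratum = sname, light_locus = locus, counts = counts,
             total = nrow(sub)),
        class = "isotype_distribution")
    }
  }
  out
}

#' @export
print.isotype_distribution <- function(x, ...) {
  cat(sprintf("isotype_distribution %s/%s (n=%d): %s\n", x$stratum,
              x$light_locus, x$total,
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Flow-cytometry index plot of sequenced cells
#'
#' Scatters two FC channels for every sorted well with index data
#' (background, grey) and overlays the sequenced, paired cells colored by
#' heavy-chain isotype. The TSV twin holds exactly the plotted values, one
#' row per well with FC data.
#'
#' @param cells cell records from [query_cells()].
#' @param store the `ig_store` holding section-3 FC index values.
#' @param x_channel,y_channel FC channel names (fatal if absent, with the
#'   available channel list in the message).
#' @param out output path stem; writes `<out>.tsv` and `<out>.<device>`.
#' @param device `"png"` or `"pdf"`.
#' @return invisibly, the TSV twin data.frame (`event_id`, x and y channel,
#'   `sequenced`, `isotype`).
#' @export
fc_index_plot <- function(cells, store, x_channel = "kappa_channel",
                          y_channel = "lambda_channel", out,
                          device = c("png", "pdf")) {
  device <- match.arg(device)
  if (device == "png" && !capabilities("png")) device <- "pdf"
  fc <- fc_wide(store)
  if (ncol(fc) <= 1L) stop("no FC channels loaded in the store")
  avail <- setdiff(names(fc), "event_id")
  for (ch in c(x_channel, y_channel)) {
    if (!ch %in% avail) {
      stop("FC channel '", ch, "' not found; available: ",
           paste(avail, collapse = ", "))
    }
  }
  paired <- cells[cells$pairing == "paired", , drop = FALSE]
  idx <- match(fc$event_id, paired$event_id)
  twin <- data.frame(event_id = fc$event_id,
                     x = fc[[x_channel]], y = fc[[y_channel]],
                     sequenced = !is.na(idx),
                     isotype = ifelse(is.na(idx), NA_character_,
                                      paired$isotype[idx]),
                     stringsAsFactors = FALSE)
  names(twin)[2:3] <- c(x_channel, y_channel)
  twin <- twin[order(twin$event_id), ]
  rownames(twin) <- NULL
  write.table(twin, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  img <- paste0(out, ".", device)
  open_device(img, width = 6, height = 6)
  x <- log10(pmax(twin[[x_channel]], 1))
  y <- log10(pmax(twin[[y_channel]], 1))
  graphics::plot(x, y, col = "grey70", pch = 16, cex = 0.6,
                 xlab = paste0("log10 ", x_channel),
                 ylab = paste0("log10 ", y_channel),
                 main = "FC index data, sequenced cells by isotype")
  seqd <- twin$sequenced
  iso <- factor(twin$isotype[seqd])
  if (length(levels(iso))) {
    pal <- grDevices::hcl.colors(max(3L, nlevels(iso)), "Dark 3")
    graphics::points(x[seqd], y[seqd], col = pal[as.integer(iso)], pch = 16,
                     cex = 0.8)
    graphics::legend("topright", legend = levels(iso),
                     col = pal[seq_len(nlevels(iso))], pch = 16, cex = 0.8)
  }
  grDevices::dev.off()
  invisible(twin)
}
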