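test_that("a fresh store has all four sections' tables and is idempotent", {
  d <- withr::local_tempdir()
  st <- init_store(d)
  expected <- c("reads", "tag_assignments",
                "consensus", "segment_assignments", "mutations",
                "chain_annotations",
                "donors", "samples", "sort_events", "fc_index_values",
                "germline_segments", "region_maps")
  for (tab in expected) {
    expect_true(file.exists(file.path(d, paste0(tab, ".tsv"))), info = tab)
    expect_equal(nrow(store_get(st, tab)), 0L, info = tab)
  }
  expect_equal(length(expected), 12L)
  # double init is a no-op
  store_append(st, "donors", data.frame(donor_id = "d1"))
  st2 <- init_store(d)
  expect_equal(store_get(st2, "donors")$donor_id, "d1")
})

test_that("a store stamped with a different version is fatal", {
  d <- withr::local_tempdir()
  init_store(d)
  writeLines("igwell-store 99", file.path(d, "VERSION"))
  expect_error(init_store(d), "incompatible store version")
})

test_that("tables round-trip through TSV with types intact", {
  d <- withr::local_tempdir()
  st <- init_store(d)
  cons <- data.frame(consensus_id = "e1|IGH|1", event_id = "e1",
                     locus = "IGH", rank = 1L, sequence = "ACGT",
                     n_reads = 5L, column_agreement = 0.975,
                     source = "consensus", stringsAsFactors = FALSE)
  store_set(st, "consensus", cons)
  fresh <- init_store(d) # new handle, forces re-read from disk
  expect_equal(store_get(fresh, "consensus"), cons)
})

test_that("metadata and FC loading resolves wells through the layout", {
  d <- withr::local_tempdir()
  st <- init_store(d)
  sch <- make_barcode_scheme(4, 4, seed = 8)
  layout <- make_plate_layout(sch, 1, 4, 4)
  meta <- data.frame(plate = 1L, row = rep(LETTERS[1:4], each = 4),
                     col = rep(1:4, 4), donor = "d1", sample = "s1",
                     sort_date = "2026-01-15",
                     empty_well = rep(c(FALSE, TRUE), 8),
                     stringsAsFactors = FALSE)
  fc <- data.frame(plate = c(rep(1L, 16), 99L),
                   row = c(rep(LETTERS[1:4], each = 4), "A"),
                   col = c(rep(1:4, 4), 1L),
                   kappa_channel = 2^seq(1, 17, length.out = 17),
                   lambda_channel = 100, stringsAsFactors = FALSE)
  counts <- load_metadata_and_fc(st, meta, fc, layout)
  expect_equal(counts$n_metadata, 16L)
  expect_equal(counts$n_fc, 16L)
  expect_equal(counts$n_unmatched_wells, 1L) # the plate-99 FC row
  expect_equal(nrow(store_get(st, "sort_events")), 16L)
  expect_equal(nrow(store_get(st, "fc_index_values")), 32L) # 2 channels
  expect_equal(store_get(st, "donors")$donor_id, "d1")
})

make_annotated_store <- function(d, light_rows) {
  st <- init_store(d)
  store_load_reference(st, toy_ref())
  cons <- data.frame(
    consensus_id = c("e1|IGH|1", paste0("e1|", light_rows$locus, "|1")),
    event_id = "e1", locus = c("IGH", light_rows$locus),
    rank = 1L, sequence = "ACGT",
    n_reads = c(6L, light_rows$n_reads), column_agreement = 1,
    source = "consensus", stringsAsFactors = FALSE)
  store_set(st, "consensus", cons)
  ann <- data.frame(
    consensus_id = cons$consensus_id, event_id = "e1", locus = cons$locus,
    rank = 1L, v_call = c("IGHV1-1*01", light_rows$v_call),
    d_call = NA, j_call = c("IGHJ1*01", light_rows$j_call), c_call = NA,
    junction = "TGTGCG", junction_aa = "CA", junction_start = 1L,
    junction_end = 6L, isotype = c("IGHG1", rep(NA, nrow(light_rows))),
    productive = TRUE, reasons = "", mutation_count = 0L, regions = "",
    flags = "", stringsAsFactors = FALSE)
  store_set(st, "chain_annotations", ann)
  st
}

test_that("query_cells joins heavy and light chains per event", {
  d <- withr::local_tempdir()
  st <- make_annotated_store(d, data.frame(
    locus = "IGK", n_reads = 4L, v_call = "IGKV1-1*01",
    j_call = "IGKJ1*01", stringsAsFactors = FALSE))
  cells <- query_cells(st)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$pairing, "paired")
  expect_equal(cells$light_locus, "IGK")
  expect_equal(cells$heavy_v_family, "IGHV1")
  expect_false(cells$light_conflict)
})

test_that("heavy-only events are flagged unpaired", {
  d <- withr::local_tempdir()
  st <- make_annotated_store(d, data.frame(
    locus = character(), n_reads = integer(), v_call = character(),
    j_call = character(), stringsAsFactors = FALSE))
  cells <- query_cells(st)
  expect_equal(cells$pairing, "heavy_only")
  expect_true(is.na(cells$light_locus))
})

test_that("dual kappa+lambda rank-1 light chains resolve by read support", {
  d <- withr::local_tempdir()
  st <- make_annotated_store(d, data.frame(
    locus = c("IGK", "IGL"), n_reads = c(3L, 7L),
    v_call = c("IGKV1-1*01", "IGLV1-1*01"),
    j_call = c("IGKJ1*01", "IGLJ1*01"), stringsAsFactors = FALSE))
  cells <- query_cells(st)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$light_locus, "IGL") # 7 > 3 reads
  expect_true(cells$light_conflict)
})

test_that("the audit passes on a consistent store and fails on orphans", {
  d <- withr::local_tempdir()
  st <- make_annotated_store(d, data.frame(
    locus = "IGK", n_reads = 4L, v_call = "IGKV1-1*01",
    j_call = "IGKJ1*01", stringsAsFactors = FALSE))
  audit <- audit_store(st)
  expect_true(attr(audit, "ok"))
  store_append(st, "mutations", data.frame(
    consensus_id = "missing|IGH|1", segment_id = "IGHV1-1*01",
    germline_pos = 1L, germline_base = "A", query_base = "C",
    kind = "substitution", region = "FR1", stringsAsFactors = FALSE))
  audit2 <- audit_store(st)
  expect_false(attr(audit2, "ok"))
  bad <- audit2[audit2$check == "mutations.consensus_id in consensus", ]
  expect_false(bad$pass)
})
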