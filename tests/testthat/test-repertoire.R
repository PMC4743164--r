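trivial_cells <- function() {
  data.frame(
    event_id = sprintf("e%d", 1:5),
    pairing = c(rep("paired", 4), "heavy_only"),
    light_conflict = FALSE,
    heavy_v_family = c("IGHV1", "IGHV1", "IGHV2", "IGHV1", "IGHV3"),
    heavy_j_family = "IGHJ1",
    light_v_family = c("IGKV1", "IGKV1", "IGKV1", "IGLV1", NA),
    light_j_family = c("IGKJ1", "IGKJ1", "IGKJ1", "IGLJ1", NA),
    heavy_v_gene = "IGHV1-1", heavy_j_gene = "IGHJ1",
    light_v_gene = "IGKV1-1", light_j_gene = "IGKJ1",
    light_locus = c("IGK", "IGK", "IGK", "IGL", NA),
    isotype = c("IGHG1", "IGHG1", "IGHG2", NA, "IGHG1"),
    donor = c("d1", "d1", "d1", "d1", "d2"),
    stringsAsFactors = FALSE)
}

test_that("pairing matrices count paired cells and normalize to 1", {
  cells <- trivial_cells()[1:3, ] # 2x (IGHV1,IGKV1), 1x (IGHV2,IGKV1)
  pm <- pairing_matrix(cells, level = "V_family")
  expect_length(pm, 1L)
  m <- pm$all
  expect_equal(sum(m$counts), 3L)
  expect_equal(as.vector(m$frequencies), c(2 / 3, 1 / 3))
  expect_equal(sum(m$frequencies), 1)
  expect_equal(rownames(m$counts), c("IGHV1", "IGHV2"))
  # a single cell gives a single entry of 1.0
  pm1 <- pairing_matrix(trivial_cells()[1, ], level = "V_family")
  expect_equal(as.vector(pm1$all$frequencies), 1)
})

test_that("unpaired cells are excluded and counted; row normalization works", {
  cells <- trivial_cells()
  pm <- pairing_matrix(cells, level = "V_family")
  expect_equal(pm$all$n_paired, 4L)
  expect_equal(pm$all$n_excluded, 1L)
  pr <- pairing_matrix(cells, level = "V_family", normalize = "row")
  expect_true(all(abs(rowSums(pr$all$frequencies) - 1) < 1e-9))
})

test_that("stratified matrices partition the paired cells", {
  cells <- trivial_cells()
  cells$donor <- c("d1", "d1", "d2", "d2", "d1")
  pm <- pairing_matrix(cells, level = "J_family", stratify_by = "donor")
  expect_equal(sort(names(pm)), c("d1", "d2"))
  expect_equal(sum(vapply(pm, function(m) sum(m$counts), 1)), 4)
  for (m in pm) expect_lt(abs(sum(m$frequencies) - 1), 1e-9)
})

test_that("isotype distributions split by light locus with unassigned bucket", {
  cells <- trivial_cells()[1:4, ]
  dist <- isotype_by_light_locus(cells, stratify_by = NULL)
  igk <- dist$all.IGK
  expect_equal(igk$total, 3L)
  expect_equal(igk$counts[["IGHG1"]], 2L)
  expect_equal(igk$counts[["IGHG2"]], 1L)
  igl <- dist$all.IGL
  expect_equal(igl$total, 1L)
  expect_equal(igl$counts[["unassigned"]], 1L)
  # a locus with no cells is emitted empty
  kap_only <- cells[cells$light_locus == "IGK", ]
  d2 <- isotype_by_light_locus(kap_only, stratify_by = NULL)
  expect_equal(d2$all.IGL$total, 0L)
  expect_length(d2$all.IGL$counts, 0L)
})

test_that("fc_index_plot requires loaded channels and writes a faithful twin", {
  st <- init_store(withr::local_tempdir())
  cells <- trivial_cells()
  expect_error(fc_index_plot(cells, st, out = tempfile()), "no FC channels")
  sch <- make_barcode_scheme(2, 3, seed = 4)
  layout <- make_plate_layout(sch, 1, 2, 3)
  fc <- data.frame(plate = 1L, row = rep(c("A", "B"), each = 3),
                   col = rep(1:3, 2), kappa_channel = c(1:6) * 100,
                   lambda_channel = 50, stringsAsFactors = FALSE)
  meta <- data.frame(plate = 1L, row = rep(c("A", "B"), each = 3),
                     col = rep(1:3, 2), donor = "d1", sample = "s1",
                     sort_date = "x", empty_well = FALSE,
                     stringsAsFactors = FALSE)
  load_metadata_and_fc(st, meta, fc, layout)
  cells$event_id <- c("exp1_p01A01", "exp1_p01A02", "exp1_p01A03",
                      "exp1_p01B01", "exp1_p01B02")
  out <- file.path(withr::local_tempdir(), "fcplot")
  twin <- fc_index_plot(cells, st, out = out)
  expect_equal(nrow(twin), 6L) # one row per sorted well with FC data
  expect_error(fc_index_plot(cells, st, x_channel = "nope", out = out),
               "available")
  expect_equal(sum(twin$sequenced), 4L) # the paired cells with FC rows
  expect_true(file.exists(paste0(out, ".tsv")))
})

test_that("sim-scale pairing frequencies are consistent with the truth table", {
  res <- cached_pipeline("clean", clean_sim())
  cells <- query_cells(res$store)
  pm <- pairing_matrix(cells, level = "V_family")$all
  expect_lt(abs(sum(pm$frequencies) - 1), 1e-9)
  expect_equal(sum(pm$counts), sum(cells$pairing == "paired"))
  tc <- clean_sim()$truth$cells
  tc <- tc[tc$event_id %in% cells$event_id[cells$pairing == "paired"], ]
  truth_counts <- table(ig_family(tc$heavy_v), ig_family(tc$light_v))
  # error-free run: matrix marginals equal the truth marginals over the
  # cells that yielded both chains (a chain can draw zero reads)
  expect_equal(rowSums(pm$counts)[rownames(truth_counts)],
               rowSums(truth_counts))
  expect_equal(colSums(pm$counts)[colnames(truth_counts)],
               colSums(truth_counts))
})
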