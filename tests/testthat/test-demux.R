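hand_scheme <- function(max_mismatch = 1L) {
  # two tags per side, pairwise Hamming distance >= 4
  barcode_scheme(
    proximal = c(P01 = "ACGTACGTAC", P02 = "TGCATGCAAC"),
    distal = c(D01 = "GGATCCGGAT", D02 = "CCTAGGTTAA"),
    max_mismatch = max_mismatch)
}

tagged_read <- function(scheme, prox = "P01", dist = "D01",
                        insert = strrep("ACGGT", 20)) {
  paste0(scheme$proximal[[prox]], insert, revcomp(scheme$distal[[dist]]))
}

test_that("exact proximal and distal tags give status both with 0 mismatches", {
  sch <- hand_scheme()
  reads <- data.frame(read_id = "r1",
                      sequence = tagged_read(sch), stringsAsFactors = FALSE)
  tags <- identify_tags(reads, sch)
  expect_equal(tags$status, "both")
  expect_equal(tags$proximal_tag, "P01")
  expect_equal(tags$distal_tag, "D01")
  expect_equal(tags$proximal_mismatches, 0L)
  expect_equal(tags$distal_mismatches, 0L)
  expect_equal(tags$proximal_offset, 1L)
  expect_equal(tags$distal_offset, nchar(reads$sequence) - 9L)
})

test_that("a tag exceeding max_mismatch is absent for that side", {
  sch <- hand_scheme()
  r <- tagged_read(sch)
  substr(r, 1, 2) <- "GT" # 2 mismatches in the proximal tag
  tags <- identify_tags(data.frame(read_id = "r1", sequence = r,
                                   stringsAsFactors = FALSE), sch)
  expect_equal(tags$status, "distal_only")
  expect_true(is.na(tags$proximal_tag))
  # one mismatch is still accepted
  r2 <- tagged_read(sch)
  substr(r2, 1, 1) <- "G"
  tags2 <- identify_tags(data.frame(read_id = "r2", sequence = r2,
                                    stringsAsFactors = FALSE), sch)
  expect_equal(tags2$status, "both")
  expect_equal(tags2$proximal_mismatches, 1L)
})

test_that("reads shorter than a tag get status none, nothing is dropped", {
  sch <- hand_scheme()
  reads <- data.frame(read_id = c("r1", "r2"),
                      sequence = c("ACGT", tagged_read(sch)),
                      stringsAsFactors = FALSE)
  tags <- identify_tags(reads, sch)
  expect_equal(tags$status, c("none", "both"))
  expect_equal(nrow(tags), nrow(reads)) # partition property at small scale
})

test_that("schemes violating the distance invariant are rejected", {
  expect_error(barcode_scheme(
    proximal = c(P01 = "ACGTACGTAC", P02 = "ACGTACGTAG"),
    distal = c(D01 = "GGATCCGGAT"), max_mismatch = 1L),
    "distance invariant")
  expect_error(barcode_scheme(
    proximal = c(P01 = "ACGTACGTAC", P02 = "ACGTA"),
    distal = c(D01 = "GGATCCGGAT")), "same length")
})

test_that("decode maps declared pairs and records unassignment reasons", {
  sch <- hand_scheme()
  layout <- plate_layout(data.frame(
    proximal_id = c("P01", "P02"), distal_id = c("D01", "D01"),
    plate = 1L, row = c("A", "B"), col = 1L, stringsAsFactors = FALSE))
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    sequence = c(tagged_read(sch, "P01", "D01"),
                 tagged_read(sch, "P01", "D02"), # pair not in layout
                 substr(tagged_read(sch, "P01", "D01"), 1, 60)),
    stringsAsFactors = FALSE)
  dec <- decode_events(identify_tags(reads, sch), layout, "expX")
  expect_equal(dec$event_id[1], "expX_p01A01")
  expect_equal(dec$plate[1], 1L)
  expect_true(is.na(dec$event_id[2]))
  expect_equal(dec$unassigned_reason[2], "unmapped_pair")
  expect_true(is.na(dec$event_id[3]))
  expect_false(is.na(dec$unassigned_reason[3]))
})

test_that("a full 16x24 scheme enumerates 384 collision-free wells", {
  sch <- make_barcode_scheme(16, 24, seed = 2)
  layout <- make_plate_layout(sch, n_plates = 1, plate_rows = 16,
                              plate_cols = 24)
  expect_equal(nrow(layout), 384L)
  expect_equal(anyDuplicated(layout[, c("proximal_id", "distal_id")]), 0L)
  expect_equal(anyDuplicated(layout[, c("plate", "row", "col")]), 0L)
  # barcode scheme round trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_scheme(sch, f)
  sch2 <- read_barcode_scheme(f)
  expect_identical(sch2$proximal, sch$proximal)
  expect_identical(sch2$distal, sch$distal)
})

test_that("error-free simulated reads all decode to their truth well", {
  sim <- clean_sim()
  tags <- identify_tags(sim$reads, sim$scheme)
  expect_true(all(tags$status == "both"))
  dec <- decode_events(tags, sim$layout)
  expect_identical(dec$event_id, sim$truth$reads$event_id)
  # status counts partition the input
  expect_equal(sum(table(tags$status)), nrow(sim$reads))
})

test_that("tag matching tolerates up to max_mismatch injected errors", {
  sim <- clean_sim()
  reads <- sim$reads[1:50, ]
  # corrupt one base inside each proximal tag
  for (i in seq_len(nrow(reads))) {
    b <- substr(reads$sequence[i], 3, 3)
    substr(reads$sequence[i], 3, 3) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  tags <- identify_tags(reads, sim$scheme)
  expect_true(all(tags$status == "both"))
  expect_true(all(tags$proximal_mismatches == 1L))
  dec <- decode_events(tags, sim$layout)
  expect_identical(dec$event_id, sim$truth$reads$event_id[1:50])
})

test_that("per-cell FASTA bypass parses well addresses and skips bad headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1|1|A|1|IGH", strrep("ACGT", 20),
               ">c2|2|B|12", strrep("TTGCA", 16),
               ">broken", strrep("ACGT", 15)), f)
  expect_warning(pc <- bypass_demux(f, "expY"), "malformed")
  expect_equal(nrow(pc), 2L)
  expect_equal(attr(pc, "n_skipped"), 1L)
  expect_equal(pc$event_id, c("expY_p01A01", "expY_p02B12"))
  expect_equal(pc$locus, c("IGH", NA_character_))
})
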