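test_that("toy reference generation is seed-deterministic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference(make_toy_reference(17), d1)
  write_reference(make_toy_reference(17), d2)
  for (f in c("v.fasta", "d.fasta", "j.fasta", "c.fasta", "regions.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ref18 <- make_toy_reference(18)
  expect_false(identical(ref18$segments$sequence,
                         make_toy_reference(17)$segments$sequence))
})

test_that("generated V segments have no in-frame stop codon", {
  vs <- toy_ref()$segments
  vs <- vs$sequence[vs$segment_type == "V"]
  for (v in vs) {
    codons <- substring(v, seq(1, nchar(v), 3), seq(3, nchar(v), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("error-free reads are exact tagged copies of germline recombinants", {
  sim <- clean_sim()
  tc <- sim$truth$cells
  tr <- sim$truth$reads
  layout <- as.data.frame(sim$layout)
  for (i in seq_len(nrow(sim$reads))) {
    row <- tr[i, ]
    cell <- tc[tc$event_id == row$event_id, ]
    transcript <- if (row$locus == "IGH") cell$heavy_sequence else
      cell$light_sequence
    expected <- paste0(sim$scheme$proximal[[row$proximal_tag]], transcript,
                       revcomp(sim$scheme$distal[[row$distal_tag]]))
    expect_identical(sim$reads$sequence[i], expected)
  }
  # transcript structure: V then junction insert then J then C
  cell <- tc[1, ]
  v <- ref_segment(toy_ref(), cell$heavy_v)$sequence
  j <- ref_segment(toy_ref(), cell$heavy_j)$sequence
  cc <- ref_segment(toy_ref(), cell$heavy_c)$sequence
  expect_identical(cell$heavy_sequence,
                   paste0(v, cell$heavy_junction, j, cc))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_plates = 1, plate_rows = 3, plate_cols = 4,
                  occupancy = 0.7, reads_per_chain_mean = 4, seed = 5)
  s1 <- simulate_repertoire(toy_ref(), p)
  s2 <- simulate_repertoire(toy_ref(), p)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$cells, s2$truth$cells)
  expect_identical(s1$fc_index, s2$fc_index)
})

test_that("read/truth conservation and FASTQ round trip hold", {
  sim <- small_sim()
  expect_equal(nrow(sim$reads), nrow(sim$truth$reads))
  expect_true(all(sim$truth$reads$event_id %in% sim$truth$cells$event_id))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, f)
  back <- read_fastq(f)
  expect_equal(back, sim$reads)
})

test_that("injected heavy-V mutation counts match the binomial model", {
  sim <- cached_sim("shm02", sim_params(
    n_plates = 1, plate_rows = 16, plate_cols = 16, occupancy = 0.8,
    reads_per_chain_mean = 4, per_base_error_rate = 0, shm_rate = 0.02,
    seed = 31))
  tc <- sim$truth$cells
  counts <- vapply(tc$heavy_mutations,
                   function(x) nrow(decode_mutations(x)), 1L)
  n_cells <- nrow(tc)
  expect_gt(n_cells, 150)
  # 300 nt V at rate 0.02 -> Binomial mean 6, se = sd / sqrt(n_cells)
  se <- sqrt(300 * 0.02 * 0.98 / n_cells)
  expect_lt(abs(mean(counts) - 6), 3 * se)
  # every recorded mutation lies within its V segment and changes the base
  m1 <- decode_mutations(tc$heavy_mutations[which(nzchar(tc$heavy_mutations))[1]])
  expect_true(all(m1$germline_pos >= 1 & m1$germline_pos <= 300))
  expect_true(all(m1$germline_base != m1$query_base))
})

test_that("FC channels separate kappa from lambda cells", {
  sim <- cached_sim("shm02", sim_params(
    n_plates = 1, plate_rows = 16, plate_cols = 16, occupancy = 0.8,
    reads_per_chain_mean = 4, per_base_error_rate = 0, shm_rate = 0.02,
    seed = 31))
  tc <- sim$truth$cells
  fc <- sim$fc_index
  key <- paste(fc$plate, fc$row, fc$col)
  idx <- match(paste(tc$plate, tc$row, tc$col), key)
  kap <- tc$light_locus == "IGK"
  expect_gt(mean(fc$kappa_channel[idx[kap]] > fc$lambda_channel[idx[kap]]),
            0.99)
  lam <- !kap
  expect_gt(mean(fc$lambda_channel[idx[lam]] > fc$kappa_channel[idx[lam]]),
            0.99)
})

test_that("zero occupancy warns and yields empty outputs", {
  p <- sim_params(n_plates = 1, plate_rows = 2, plate_cols = 2,
                  occupancy = 0, seed = 1)
  expect_warning(sim <- simulate_repertoire(toy_ref(), p), "no occupied")
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(nrow(sim$truth$cells), 0L)
})

test_that("sim parameter validation rejects bad inputs", {
  expect_error(sim_params(occupancy = 1.2))
  expect_error(sim_params(isotype_weights = c(IGHG1 = 0.5, IGHG2 = 0.4)),
               "sum to 1")
})
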