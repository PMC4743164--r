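test_that("exact V+J concatenation is assigned with identity 1", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  a <- assign_segments(paste0(v, "GG", j), ref)
  expect_false(a$unannotatable)
  expect_equal(a$v$segment_id, "IGHV1-1*01")
  expect_equal(a$v$alignment$identity, 1.0)
  expect_equal(a$j$segment_id, "IGHJ1*01")
  expect_equal(a$j$alignment$identity, 1.0)
  expect_equal(a$locus, "IGH")
  expect_null(a$d) # the 2 nt spacer is below the 5 nt D minimum
})

test_that("sequences without a V hit above threshold are unannotatable", {
  set.seed(3)
  a <- assign_segments(random_dna(60), toy_ref())
  expect_true(a$unannotatable)
  expect_null(a$v)
  ann <- annotate_chain(random_dna(60), toy_ref())
  expect_false(ann$productive)
  expect_equal(ann$reasons, "unannotatable")
})

test_that("D segments are assigned inside real heavy transcripts", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV2-1*01")$sequence
  d <- ref_segment(ref, "IGHD1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ2*01")$sequence
  a <- assign_segments(paste0(v, "AA", d, "TT", j), ref)
  expect_equal(a$d$segment_id, "IGHD1-1*01")
  expect_gte(a$d$alignment$n_aligned_cols, 5L)
  # ordering invariant: v <= d <= j on the query with <= 4 nt overlap
  expect_lte(a$v$alignment$query_end - 4L, a$d$alignment$query_start)
  expect_lte(a$d$alignment$query_end, a$j$alignment$query_start)
})

test_that("region projection follows the V alignment offset and indels", {
  ref <- mini_ref()
  v <- mini_seg("IGHV9-1*01")
  j <- mini_seg("IGHJ9*01")
  # gapless full-length alignment starting at query position 1
  s1 <- paste0(v, "GGG", j)
  a1 <- assign_segments(s1, ref)
  r1 <- annotate_regions(s1, a1, ref)
  expect_equal(r1$regions$start[r1$regions$region == "FR1"], 1L)
  expect_equal(r1$regions$end[r1$regions$region == "FR1"], 30L)
  # a 10 nt 5' pad shifts every region by 10
  s2 <- paste0("TTTTTTTTTT", v, "GGG", j)
  a2 <- assign_segments(s2, ref, extend_ends = FALSE)
  r2 <- annotate_regions(s2, a2, ref)
  expect_equal(r2$regions$start[r2$regions$region == "FR1"], 11L)
  expect_equal(r2$regions$end[r2$regions$region == "FR1"], 40L)
  # a 3 nt insertion inside FR2 shifts downstream boundaries by 3
  v_ins <- paste0(substr(v, 1, 50), "AAA", substr(v, 51, nchar(v)))
  s3 <- paste0(v_ins, "GGG", j)
  a3 <- assign_segments(s3, ref)
  r3 <- annotate_regions(s3, a3, ref)
  fr2 <- r3$regions[r3$regions$region == "FR2", ]
  cdr2 <- r3$regions[r3$regions$region == "CDR2", ]
  expect_equal(fr2$start, 41L)
  expect_equal(fr2$end, 60L + 3L)
  expect_equal(cdr2$start, 61L + 3L)
  # junction runs from after projected FR3 through the first J codon
  expect_equal(unname(r1$junction["start"]), 85L)
  expect_equal(unname(r1$junction["end"]),
               a1$j$alignment$query_start + 2L)
})

test_that("projected regions plus junction tile the query without overlap", {
  ref <- toy_ref()
  sim <- clean_sim()
  for (i in 1:5) {
    s <- sim$truth$cells$heavy_sequence[i]
    ann <- annotate_chain(s, ref)
    iv <- rbind(ann$regions[, c("start", "end")],
                data.frame(start = ann$junction[["start"]],
                           end = ann$junction[["end"]]))
    iv <- iv[order(iv$start), ]
    expect_true(all(iv$start[-1] == head(iv$end, -1) + 1L))
  }
})

test_that("a truncated V alignment leaves the junction undefined", {
  ref <- mini_ref()
  s <- substr(mini_seg("IGHV9-1*01"), 1, 60) # stops inside FR2
  a <- assign_segments(s, ref, min_scores = c(V = 40L, J = 20L, D = 10L,
                                              C = 30L))
  r <- annotate_regions(s, a, ref)
  expect_null(r$junction)
  expect_true("truncated_v" %in% r$flags)
  ann <- list(seq = s, assignment = a, junction = NULL)
  expect_false(classify_productive(ann)$productive)
})

test_that("mutation calling recovers constructed substitutions exactly", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  clean <- paste0(v, "GGGGGG", j)
  a <- assign_segments(clean, ref)
  expect_equal(nrow(call_mutations(clean, a, ref)), 0L)
  # single substitution at germline V position 42
  mutated <- clean
  from <- substr(v, 42, 42)
  to <- setdiff(c("A", "C", "G", "T"), from)[1]
  substr(mutated, 42, 42) <- to
  m <- call_mutations(mutated, assign_segments(mutated, ref), ref)
  expect_equal(nrow(m), 1L)
  expect_equal(m$segment_id, "IGHV1-1*01")
  expect_equal(m$germline_pos, 42L)
  expect_equal(m$germline_base, from)
  expect_equal(m$query_base, to)
  expect_equal(m$kind, "substitution")
  expect_equal(m$region, "FR1") # toy map: FR1 spans germline 1..75
})

test_that("mutations at the first and last V base are not clipped", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  s <- paste0(v, "GGGGGG", j)
  for (pos in c(1L, nchar(v))) {
    mut <- s
    from <- substr(v, pos, pos)
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"), from)[1]
    m <- call_mutations(mut, assign_segments(mut, ref), ref)
    expect_equal(m$germline_pos, pos)
  }
})

test_that("junction bases never produce mutation calls", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  s <- paste0(v, "GGGGGG", j)
  mut <- s
  substr(mut, nchar(v) + 3L, nchar(v) + 3L) <- "T" # inside the N insert
  m <- call_mutations(mut, assign_segments(mut, ref), ref)
  expect_equal(nrow(m), 0L)
})

test_that("N query bases are never reported as mutations", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  s <- paste0(v, "GGGGGG", j)
  substr(s, 10, 10) <- "N"
  m <- call_mutations(s, assign_segments(s, ref), ref)
  expect_equal(nrow(m), 0L)
})

test_that("every reference segment self-aligns with zero mutations", {
  ref <- toy_ref()
  vs <- ref$segments[ref$segments$segment_type == "V", ]
  for (i in seq_len(nrow(vs))) {
    a <- assign_segments(vs$sequence[i], ref)
    expect_equal(a$v$segment_id, vs$segment_id[i])
    expect_equal(nrow(call_mutations(vs$sequence[i], a, ref)), 0L)
  }
})

test_that("isotype assignment needs sufficient constant region", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  g1 <- ref_segment(ref, "IGHG1*01")$sequence
  s_full <- paste0(v, "GGG", j, substr(g1, 1, 60))
  a <- assign_segments(s_full, ref)
  expect_equal(assign_isotype(s_full, a, ref), "IGHG1")
  s_short <- paste0(v, "GGG", j, substr(g1, 1, 20))
  a2 <- assign_segments(s_short, ref)
  expect_true(is.na(assign_isotype(s_short, a2, ref)))
})

test_that("subclass discrimination and class-level ties behave as specified", {
  ref <- mini_ref() # IGHG8 and IGHG9 differ at constant position 30 only
  v <- mini_seg("IGHV9-1*01"); j <- mini_seg("IGHJ9*01")
  c9 <- mini_seg("IGHG9*01")
  s <- paste0(v, "GGG", j, substr(c9, 1, 40)) # covers the discriminating base
  a <- assign_segments(s, ref)
  expect_equal(assign_isotype(s, a, ref), "IGHG9")
  # a fragment stopping short of position 30 cannot separate the subclasses
  s2 <- paste0(v, "GGG", j, substr(c9, 1, 29))
  a2 <- assign_segments(s2, ref, min_scores = c(V = 60L, J = 20L, D = 10L,
                                                C = 20L))
  expect_equal(assign_isotype(s2, a2, ref, min_c_len = 25L), "IGHG")
})

test_that("productivity requires an in-frame, stop-free junction", {
  ref <- toy_ref()
  v <- ref_segment(ref, "IGHV1-1*01")$sequence
  j <- ref_segment(ref, "IGHJ1*01")$sequence
  # junction = V tail (289..300) + insert + first J codon; V FR3 ends at 288
  in_frame <- annotate_chain(paste0(v, "GGGGGG", j), ref)
  expect_true(in_frame$productive)
  expect_equal((in_frame$junction[["end"]] - in_frame$junction[["start"]] +
                  1L) %% 3L, 0L)
  out_frame <- annotate_chain(paste0(v, "GGGG", j), ref)
  expect_false(out_frame$productive)
  expect_true("out_of_frame" %in% out_frame$reasons)
  stopped <- annotate_chain(paste0(v, "TAAGGG", j), ref)
  expect_false(stopped$productive)
  expect_true("stop_codon" %in% stopped$reasons)
})

test_that("gene assignment is accurate on noisy reads at small scale", {
  sim <- small_sim()
  ref <- toy_ref()
  tr <- sim$truth$reads
  tc <- sim$truth$cells
  idx <- seq_len(min(60L, nrow(sim$reads)))
  plen <- nchar(sim$scheme$proximal[[1]])
  hits <- 0L
  for (i in idx) {
    seqv <- substr(sim$reads$sequence[i], plen + 1L,
                   nchar(sim$reads$sequence[i]) - plen)
    a <- assign_segments(seqv, ref)
    cell <- tc[tc$event_id == tr$event_id[i], ]
    truth_v <- if (tr$locus[i] == "IGH") cell$heavy_v else cell$light_v
    truth_j <- if (tr$locus[i] == "IGH") cell$heavy_j else cell$light_j
    hits <- hits + (identical(ig_gene(a$v$segment_id), ig_gene(truth_v)) &&
                      identical(ig_gene(a$j$segment_id), ig_gene(truth_j)))
  }
  expect_gte(hits / length(idx), 0.98)
})
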