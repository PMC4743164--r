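read_tbl <- function(v, j, score = 100, n = length(v)) {
  data.frame(read_id = sprintf("r%02d", seq_len(n)), v_gene = v, j_gene = j,
             v_score = rep_len(score, n), stringsAsFactors = FALSE)
}

test_that("read groups are ranked by support with score tie-break", {
  tbl <- read_tbl(c(rep("IGHV1-1", 6), rep("IGHV2-1", 3)), "IGHJ1")
  g <- group_reads(tbl)
  expect_equal(g$support, c(6L, 3L))
  expect_equal(g$v_gene, c("IGHV1-1", "IGHV2-1"))
  expect_equal(g$rank, 1:2)
  # 3 vs 3 reads: summed V score decides
  tbl2 <- data.frame(read_id = sprintf("r%d", 1:6),
                     v_gene = rep(c("IGHV1-1", "IGHV2-1"), each = 3),
                     j_gene = "IGHJ1",
                     v_score = c(190, 190, 200, 190, 190, 180),
                     stringsAsFactors = FALSE)
  g2 <- group_reads(tbl2)
  expect_equal(g2$v_gene[g2$rank == 1], "IGHV1-1") # 580 vs 560
  # a single read still forms a rank-1 group
  g3 <- group_reads(read_tbl("IGHV1-1", "IGHJ1", n = 1))
  expect_equal(g3$support, 1L)
  expect_equal(g3$rank, 1L)
})

test_that("groups beyond rank 2 and ineligible reads are counted, not lost", {
  tbl <- read_tbl(c(rep("IGHV1-1", 4), rep("IGHV2-1", 3), rep("IGHV3-1", 2),
                    NA),
                  c(rep("IGHJ1", 9), NA))
  g <- group_reads(tbl)
  expect_equal(nrow(g), 2L)
  expect_equal(attr(g, "n_excluded"), 1L)
  expect_equal(attr(g, "n_discarded_groups"), 1L)
  # conservation: supports + excluded + discarded-group reads = total
  expect_equal(sum(g$support) + attr(g, "n_excluded") + 2L, nrow(tbl))
})

test_that("consensus of identical reads is that read, for any group size", {
  s <- strrep("ACGGTCA", 12)
  for (n in c(1L, 2L, 3L, 5L)) {
    cr <- build_consensus(setNames(rep(s, n), sprintf("r%d", 1:n)))
    expect_equal(cr$sequence, s)
    expect_equal(cr$column_agreement, 1.0)
    expect_equal(cr$n_reads, n)
    expect_equal(cr$source, if (n == 1L) "single_read" else "consensus")
  }
})

test_that("majority vote restores a single-read substitution", {
  s <- strrep("ACGGTCA", 12)
  bad <- s
  substr(bad, 40, 40) <- "A" # reference base at 40 is not A
  cr <- build_consensus(c(r1 = s, r2 = s, r3 = bad))
  expect_equal(cr$sequence, s)
  expect_lt(cr$column_agreement, 1.0)
  # with 2 reads the tie goes to the center (higher V score wins centering)
  cr2 <- build_consensus(c(r1 = s, r2 = bad), v_scores = c(200, 100))
  expect_equal(cr2$sequence, s)
})

test_that("single-read indels relative to the center are dropped by gap majority", {
  s <- strrep("ACGGTCA", 12)
  ins <- paste0(substr(s, 1, 40), "T", substr(s, 41, nchar(s)))
  del <- paste0(substr(s, 1, 39), substr(s, 41, nchar(s)))
  cr <- build_consensus(c(r1 = s, r2 = s, r3 = ins, r4 = del))
  expect_equal(cr$sequence, s)
})

test_that("oversized groups are subsampled deterministically", {
  s <- strrep("ACGT", 25)
  reads <- setNames(rep(s, 40), sprintf("r%03d", 1:40))
  c1 <- build_consensus(reads, max_reads = 10L, subsample_seed = 3L)
  c2 <- build_consensus(reads, max_reads = 10L, subsample_seed = 3L)
  expect_true(c1$capped)
  expect_equal(c1$n_reads, 10L)
  expect_identical(c1, c2)
})

test_that("secondary consensus requires support and a distinct V-J key", {
  s1 <- strrep("ACGGTCA", 12)
  s2 <- strrep("TTGACCA", 12)
  tbl <- data.frame(read_id = sprintf("r%d", 1:5),
                    v_gene = c(rep("IGHV1-1", 3), rep("IGHV2-1", 2)),
                    j_gene = "IGHJ1", v_score = 100,
                    stringsAsFactors = FALSE)
  seqs <- c(r1 = s1, r2 = s1, r3 = s1, r4 = s2, r5 = s2)
  g <- group_reads(tbl)
  sec <- build_secondary(g, seqs)
  expect_equal(sec$sequence, s2)
  expect_equal(sec$n_reads, 2L)
  # support 1 at the default threshold of 2 yields no secondary
  tbl1 <- tbl[1:4, ]
  sec1 <- build_secondary(group_reads(tbl1), seqs[1:4])
  expect_null(sec1)
})

test_that("re-annotating a consensus reproduces the group's V-J key", {
  sim <- clean_sim()
  ref <- toy_ref()
  res <- cached_pipeline("clean", sim)
  cons <- store_get(res$store, "consensus")
  ann <- store_get(res$store, "chain_annotations")
  ra <- merge(cons[cons$rank == 1L, c("consensus_id", "sequence")],
              ann[, c("consensus_id", "v_call", "j_call")])
  for (i in seq_len(min(10L, nrow(ra)))) {
    a <- assign_segments(ra$sequence[i], ref)
    expect_equal(ig_gene(a$v$segment_id), ig_gene(ra$v_call[i]))
    expect_equal(ig_gene(a$j$segment_id), ig_gene(ra$j_call[i]))
  }
})
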