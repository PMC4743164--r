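# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

toy_ref <- function() {
  if (is.null(.fixtures$ref)) .fixtures$ref <- make_toy_reference(17)
  .fixtures$ref
}

cached_sim <- function(key, params) {
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_repertoire(toy_ref(), params)
  }
  .fixtures[[key]]
}

# a compact simulation reused by demux / consensus / pipeline tests
small_sim <- function() {
  cached_sim("small", sim_params(
    n_plates = 1, plate_rows = 4, plate_cols = 6, occupancy = 0.8,
    reads_per_chain_mean = 6, per_base_error_rate = 0.005,
    shm_rate = 0.01, seed = 11))
}

clean_sim <- function() {
  cached_sim("clean", sim_params(
    n_plates = 1, plate_rows = 6, plate_cols = 8, occupancy = 0.8,
    reads_per_chain_mean = 5, per_base_error_rate = 0, shm_rate = 0,
    seed = 7))
}

run_sim_pipeline <- function(sim, seed = 5, stop_after = NULL,
                             store_path = NULL, out_dir = NULL) {
  if (is.null(store_path)) store_path <- tempfile("store")
  if (is.null(out_dir)) out_dir <- tempfile("out")
  cfg <- pipeline_config(
    branch = "ngs", store_path = store_path, out_dir = out_dir,
    ref = toy_ref(), reads = sim$reads, scheme = sim$scheme,
    layout = sim$layout, metadata = sim$metadata, fc = sim$fc_index,
    seed = seed, render_plots = FALSE)
  res <- run_pipeline(cfg, stop_after = stop_after)
  res$config <- cfg
  res
}

cached_pipeline <- function(key, sim, ...) {
  rkey <- paste0("pipe_", key)
  if (is.null(.fixtures[[rkey]])) {
    .fixtures[[rkey]] <- run_sim_pipeline(sim, ...)
  }
  .fixtures[[rkey]]
}

# a tiny hand-sized germline reference for constructed vdj examples:
# one 90 nt V with a full region map, one J, two constant regions that
# differ at a single position.
mini_ref <- function() {
  if (!is.null(.fixtures$mini)) return(.fixtures$mini)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(99)
  nonstop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                           paste0), c("A","C","G","T"), paste0)),
                     c("TAA", "TAG", "TGA"))
  v <- paste(sample(nonstop, 30, replace = TRUE), collapse = "")
  j <- paste(sample(nonstop, 10, replace = TRUE), collapse = "")
  c1 <- paste(sample(nonstop, 20, replace = TRUE), collapse = "")
  c2chars <- strsplit(c1, "")[[1]]
  c2chars[30] <- setdiff(c("A", "C", "G", "T"), c2chars[30])[1]
  c2 <- paste(c2chars, collapse = "")
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  segments <- data.frame(
    segment_id = c("IGHV9-1*01", "IGHJ9*01", "IGHG8*01", "IGHG9*01"),
    locus = "IGH",
    segment_type = c("V", "J", "C", "C"),
    sequence = c(v, j, c1, c2),
    stringsAsFactors = FALSE)
  region_map <- data.frame(
    segment_id = "IGHV9-1*01",
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
    start = c(1L, 31L, 41L, 61L, 71L),
    end = c(30L, 40L, 60L, 70L, 84L),
    stringsAsFactors = FALSE)
  .fixtures$mini <- germline_reference(segments, region_map, "synthetic")
  .fixtures$mini
}

mini_seg <- function(id) ref_segment(mini_ref(), id)$sequence
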