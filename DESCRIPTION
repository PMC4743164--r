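Package: igwell
Title: Single-Cell Immunoglobulin Repertoire Processing from
    Plate-Barcoded Amplicon Reads
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes immunoglobulin (Ig) amplicon sequencing reads from
    plate-sorted single B cells. Reads carrying two-dimensional (proximal +
    distal) well barcodes are demultiplexed to single-cell events, grouped
    by the most frequent V-J segment combination, and collapsed into
    error-corrected primary (and, where supported, secondary) consensus
    sequences. A built-in affine-gap local alignment engine assigns germline
    V, D, J and constant segments, projects framework and CDR regions onto
    the query, calls somatic hypermutations per germline base, assigns the
    heavy-chain isotype and determines productivity. Results, flow-cytometry
    index data and experiment metadata are stored in a four-section
    relational datastore from which heavy:light chain pairing tables,
    isotype distributions and quality-control reports are derived. A
    synthetic-data generator simulates plated repertoires with known ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    S4Vectors,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
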