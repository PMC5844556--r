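Package: cbscaffold
Title: Contig Scaffolding with Competitive-Binding Optical DNA Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places assembled sequence contigs on a consensus optical DNA map
    ("barcode") of a circular plasmid. Contig sequences are converted into
    theoretical competitive-binding barcodes by a two-ligand (YOYO-1 vs
    netropsin) transfer-matrix equilibrium on the basepair lattice, blurred by
    the optical point spread function and sampled to pixel resolution. Each
    contig barcode is scored against the reference by sliding Pearson
    correlation over all positions and both orientations; scores are converted
    to calibrated p-values via an autocorrelation-matched random-barcode null
    with a parametric max-correlation density; significant matches become
    interval bids and an exact combinatorial-auction dynamic program places
    contigs without overlap. A synthetic-data module generates random genomes,
    truncated-exponential contig cuts and pseudo-experimental reference
    barcodes for end-to-end calibration studies.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
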