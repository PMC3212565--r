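Package: replowpass
Title: Repeat Identification and Quantification from Low-Pass Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo identification of repetitive DNA from low-coverage shotgun
    sequencing by graph-based clustering of long reads, quantification of repeat
    genome proportions from short-read sequence tags with spike-in calibration
    and GC-bias diagnostics, reconstruction of circular satellite consensus
    monomers from k-mer frequency spectra, and windowed repeat annotation of
    genomic query sequences. Includes a synthetic-genome simulator that plants
    repeat families at known proportions in male/female genome pairs so every
    step of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    data.table,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
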