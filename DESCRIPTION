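Package: pyroclean
Title: Cleaning, Duplicate Removal and Paired-End Splitting for 454
    Pyrosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filters and repairs reads from 454-style long-read
    pyrosequencing runs. Detects artificial duplicate reads (multiple
    reads emitted for a single DNA fragment) by co-start alignment and
    connected-component clustering, keeping only the longest read per
    cluster; locates the paired-end linker inside reads and splits them
    into validated mate pairs or salvaged single reads; applies basic
    length, compression-based complexity, quality and undetermined-base
    filters. Reads FASTQ, FASTA (with optional .qual sidecar) and SFF v1
    flowgram files. Includes a shotgun-read simulator implementing the
    random-fragmentation duplication null model for calibrating expected
    duplication rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
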