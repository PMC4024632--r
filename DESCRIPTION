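Package: pirnakit
Title: Population Statistics and Biogenesis Simulation for piRNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising small-RNA (piRNA) libraries the way
    Piwi-protein identity is assigned from deep-sequencing data: collapsing
    of raw reads into counted unique sequences, exact-match placement onto
    transposon consensus sequences on both strands, read-length and
    positional nucleotide-bias statistics (1U and 10A), per-transposon
    strand-bias profiling, the 10-nt 5'-5' overlap (Ping-pong) signature
    with a peak z-score, and cross-library fivefold-enrichment read
    sorting. A mechanistic simulator of primary (1U-biased, antisense)
    and secondary (slicer-coupled, 10-nt overlap) piRNA biogenesis
    provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
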