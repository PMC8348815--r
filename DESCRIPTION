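Package: tdnalocus
Title: Resolution of T-DNA Insertion Loci from Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing transgene (T-DNA) insertion loci in
    plant genomes from noisy long reads (Oxford Nanopore style). Identifies
    reads carrying T-DNA or binary-vector-backbone sequence with a built-in
    seed-and-extend local aligner, tiles reads with greedy score-sorted
    annotation against a reference catalog, clusters reads into insertion
    loci, reconstructs T-DNA array structures (unit chains, border status,
    inverted-repeat rescue), classifies genome-level events (canonical
    insertions, complex arrays, chromosome translocation fusions, T-DNA-free
    compensating fusions, inverted duplications, organellar DNA capture),
    analyses junctions for filler DNA and microhomology with a cascaded
    short-match search, estimates locus zygosity from spanning-read counts,
    flags candidate reference misassemblies from alignment-end pileups, and
    profiles binned coverage for copy-number changes. A deterministic read
    simulator with planted structural events and per-read truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
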