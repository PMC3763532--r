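Package: mircluster
Title: Origin and Evolution of MicroRNA Genomic Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how genomic clusters of microRNAs arise and
    evolve. Calls clusters of microRNA precursors from genomic coordinates
    using a same-strand inter-precursor distance rule, quantifies
    co-expression of neighbouring microRNAs as a function of genomic
    distance, infers the age of each microRNA on a species phylogeny under
    Dollo parsimony, and classifies the founding event of each cluster
    (tandem duplication, de novo hairpin birth in an existing transcript,
    fusion of pre-existing loci, or unknown). Includes a birth-death
    simulator of microRNA repertoires evolving along a species tree with a
    ground-truth event log for recovery experiments, a packaged fixture of
    21 Drosophila melanogaster clusters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
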