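Package: evehunter
Title: Detection, Reconstruction and Classification of Caulimovirid
    Endogenous Viral Elements in Plant Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-branch workflow for mining endogenous viral elements
    (EVEs) of the plant pararetrovirus family Caulimoviridae from genome
    assemblies. Branch A builds a caulimovirid-enriched sub-genome by
    translated homology search, reconstructs repeat consensus sequences,
    screens them for transposable-element chimeras by protein domain
    scanning, classifies and clusters them, and annotates the genome with
    the selected library, reporting a genome coverage estimate. Branch B
    mines reverse-transcriptase (RT) loci, translates and filters them
    against a mixed caulimovirid/retroelement RT panel, dereplicates them
    by greedy identity clustering, and places representatives in a
    bootstrapped neighbour-joining phylogeny for genus-rank
    classification. All homology search, alignment, trimming and
    consensus steps are built in and deterministic, and a synthetic
    genome generator with exact ground truth makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
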