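Package: plastevol
Title: Comparative Plastome Degradation and Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genome (plastome)
    degradation in heterotrophic and carnivorous plants: quadripartite
    structure and inverted-repeat detection, coverage-based intact versus
    pseudogene classification of plastid genes against a reference CDS set
    (including the coordinated ndh-gene rule), short-repeat landscapes with
    Karlin-Altschul E-values, reference-based insertion/deletion and
    species-specific fragment quantification, FPKM expression summaries and
    C-to-U RNA-editing site calling from strand-specific pileups, MG94 codon
    branch and branch-site models with likelihood-ratio tests and a
    relaxed/strengthened selection classification, Nei-Gojobori dN/dS, and a
    synthetic plastome/alignment/counts/pileup generator with planted ground
    truth so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    car,
    ape,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
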