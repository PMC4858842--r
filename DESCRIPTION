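Package: mulescout
Title: Discovery, Dating and Epigenomic Profiling of Mutator-Like
    Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates non-autonomous Mutator-like transposable elements
    (MULEs) in plant genomes from terminal-inverted-repeat (TIR) evidence,
    validating candidate elements by target-site-duplication (TSD) rules and
    transposase screens, and classifying genic elements and MULE-derived
    putative genes.  Traces the parental (donor) loci of captured gene
    fragments, dates elements by Dollo-parsimony presence/absence on a
    species tree and by Kimura two-parameter divergence of paralogous
    copies (T = k/2r), and estimates selective constraint with
    Nei-Gojobori Ka/Ks counting.  Region-level bisulfite methylation
    summaries (CG/CHG/CHH), 24-nt small-RNA occupancy, TE content, TIR
    similarity, Marey-map LOESS recombination rates and expression-bias
    tests profile elements by evolutionary age.  A seeded synthetic-genome
    generator plants ground-truthed elements on a phylogeny so every stage
    of the pipeline is verifiable end to end.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
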