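Package: codonbias
Title: Codon Usage Bias, Codon-Pair Covariation, and Taxonomic
    Classification of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of synonymous codon usage in coding
    sequences. Computes relative synonymous codon usage (RSCU) profiles per
    sequence and per species, separates GC-content from domain-of-life
    signatures by principal component analysis, and classifies sequences
    into Archaea, Bacteria or Eukarya with a class-weighted support vector
    machine. Quantifies within-transcript codon autocorrelation with a
    binomial Z statistic and with the relative synonymous codon pair usage
    (RSCPU) ratio, calls optimal and nonoptimal codons from
    expression-stratified codon usage, and measures the overlap between
    autocorrelated codon pairs and codon optimality. A seeded multi-species
    coding-sequence simulator with tunable GC content, arginine codon
    signatures, expression-coupled codon optimality and codon-pair
    stickiness supports calibration and end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    pROC,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
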