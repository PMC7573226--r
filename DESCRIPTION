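Package: paraselect
Title: Comparative Evolution of Duplicated Gene Families: Differential
    Substitutions, Gene Dosage, Site-Model Selection and Micro-Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular-evolution analysis of duplicated
    gene families, motivated by the recruitment of paralogous enzyme subunits
    into C4 photosynthesis. Implements strict differential-substitution
    scanning of protein alignments against a designated foreground partition,
    a per-species gene-dosage census with an exact contingency test, codon
    alignment preparation (back-translation, codon-coverage filtering,
    codon-position extraction), GY94 codon site-class models (M0-M8a) with
    Felsenstein pruning likelihoods, likelihood-ratio tests and empirical
    Bayes identification of positively selected sites, and a windowed
    collinear-anchor micro-synteny classifier for duplicated loci. A synthetic
    data generator produces codon alignments evolved under site-class omega
    mixtures, planted convergent substitutions, dosage tables and
    whole-genome-duplication gene orders so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
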