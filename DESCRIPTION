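Package: plastocomp
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular quadripartite
    chloroplast genomes: inverted-repeat detection and LSC/IRb/SSC/IRa
    partitioning with junction-gene profiling, detection and classification
    of tandem, dispersed and palindromic repeats, annotation-anchored
    extraction and progressive alignment of homologous coding and noncoding
    regions, p-distance and variability statistics with hypervariable
    marker ranking, simple indel coding, maximum-parsimony phylogenetics
    (Fitch length, exhaustive and heuristic search, bootstrap, majority-rule
    consensus, homoplasy indices), and a fully seeded synthetic plastome
    simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
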