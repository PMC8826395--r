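Package: hgtrace
Title: Sequence-Divergence and Composition Evidence for Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the computational evidence chain used to
    argue that a gene family entered a lineage by horizontal gene transfer
    (HGT). Implements an accumulated-genetic-divergence (AGD) statistic built
    on bit-score densities with control-panel outlier testing, a k-mer
    spectrum sliding-window scan for compositionally anomalous genomic
    segments, residue-level synapomorphy typing of peptidylarginine deiminase
    (PADI) sequences, a penalized least-squares strict-clock root-age
    estimator with fossil calibrations, taxonomic homolog-survey tabulation,
    and seeded simulators (protein families under vertical descent, EGT and
    HGT scenarios; genomes with inserted compositional islands; clock-like
    trees) so every stage runs end to end with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
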