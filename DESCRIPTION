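Package: metaGSim
Title: Simulating Selective Genotyping Strategies for Multi-Breed Beef
    Cattle Evaluation with Metafounders
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a multi-breed beef
    cattle breeding programme (historical linkage-disequilibrium phase,
    population expansion, breed formation, and generations of selection on
    pedigree-BLUP breeding values), together with the genetic evaluation
    machinery needed to compare selective genotyping designs: pedigree
    BLUP with unknown-parent groups, and single-step genomic BLUP with
    metafounders (gamma-augmented pedigree, genomic and combined
    relationship matrices). Provides an experiment driver that crosses
    genotyping scenarios with phenotyping cases and reports the accuracy
    of predicted breeding values of selection candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, GenomicVariation, Software
RoxygenNote: 7.3.3
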