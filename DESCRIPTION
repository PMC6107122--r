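Package: forensat
Title: Forensic Microsatellite Genotyping and Population Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for wildlife molecular forensics with multi-allelic
    microsatellite (STR) panels: replicate-based consensus genotype and sex
    calling with allelic-dropout and false-allele rate estimation,
    probability-of-identity statistics and individual matching against a
    reference database, Weir-Cockerham F_ST, Nei distance with UPGMA outlier
    screening, Bayesian admixture-model clustering (Gibbs sampler) with
    Evanno delta-K model selection and cross-run Q-matrix alignment,
    frequency-based and Bayesian population assignment, discriminant analysis
    of principal components (DAPC), and a thresholded multi-method consensus
    rule for final geographic assignment of samples of unknown origin.
    Includes a Balding-Nichols simulator for generating reference populations,
    forensic queries and replicate-level PCR data with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
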