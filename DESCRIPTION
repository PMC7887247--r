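Package: memfc
Title: Pairwise Maximum Entropy Models of Binarized iEEG Power States and
    Structure-Function Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking intracranial EEG functional dynamics to white-matter
    structural connectivity. Converts multichannel recordings into binarized
    band-power states (wavelet decomposition, montage re-referencing, z-score
    thresholding), fits pairwise maximum entropy (Ising) models by
    pseudo-likelihood or exact gradient ascent, computes comparison functional
    connectivity estimators (co-activation, Pearson and partial correlation,
    PLV, PLI, WPLI), builds distance-preserving geometric structural-connectome
    nulls, and evaluates structure-function coupling with ROC/AUC, one-sided
    permutation tests and FDR correction. Includes a fully synthetic cohort
    generator with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
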