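Package: mifcdyn
Title: Mutual-Information Functional Connectivity and Brain-State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A task-fMRI analysis chain for parcellated BOLD timeseries:
    pairwise mutual-information functional connectivity (miFC) over whole
    tasks, condition-restricted volume sets, and condition-versus-neutral
    contrasts; template-network brain-state assignment from Hilbert phase
    coherence with lifetime, probability, Lempel-Ziv (LZ76),
    block-decomposition and transition-entropy dynamics metrics; edge-wise
    two-group permutation inference with max-T familywise correction; and
    partial least squares mapping of receptor-availability maps onto
    group-difference maps with variable-importance-in-projection scores and
    spatial spin-permutation nulls. A synthetic-cohort generator with
    plantable group, condition and state-dynamics effects makes every stage
    testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
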