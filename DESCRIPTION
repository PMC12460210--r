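Package: netlearn
Title: EEG Functional Connectivity Analysis of Rapid Bimanual Visuomotor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short-term changes in EEG functional
    connectivity during bimanual visuomotor tracking. Estimates band-wise
    corrected imaginary phase-locking value (ciPLV) connectivity from
    sliding-window cross-spectra, prunes weak edges by percolation
    thresholding, computes weighted closeness centrality, detects
    between-session subnetwork differences with the network-based statistic
    (paired sign-flip permutations), and links node metrics to bimanual
    tracking performance through partial Spearman screening and
    principal-component regression with leave-one-out cross-validation.
    Includes seeded generators for synthetic coupled EEG, paired pre/post
    connectivity cohorts, and tracking behavior, so every stage is testable
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
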