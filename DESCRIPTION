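Package: nigradev
Title: Postnatal Development of Morphology and Action Potential Shape in
    Nigral Dopaminergic Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the postnatal maturation of substantia nigra
    pars compacta dopaminergic neurons. Provides branched-morphology
    representation and SWC input/output, dendritic morphometry with
    axon-bearing versus non-axon-bearing dendrite decomposition, a
    stage-typed synthetic morphology generator, multicompartment
    Hodgkin-Huxley simulation on branched cables with homogeneous or
    heterogeneous dendritic conductance schemes, action-potential waveform
    decomposition (threshold, half-width, initial-segment and
    somatodendritic second-derivative components), sodium-conductance
    screening, and the multivariate developmental-stage statistics
    (stage comparisons, statistical stacking, hierarchical clustering,
    linear discriminant analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
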