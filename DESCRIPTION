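Package: aisgeom
Title: Axon Initial Segment Geometry and Predicted Excitability in
    Hippocampal Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of proximal pyramidal-cell geometry in the
    hippocampus (axon initial segment length, position and diameter, soma and
    apical dendrite size, axon-carrying-dendrite classification), a
    Gaussian-copula synthetic cohort generator reproducing the statistical
    structure of measured cohorts, and a reduced conductance-based
    multicompartment CA1 neuron model (branched cable equation, implicit
    fixed-step integration) used to predict input thresholds, somatic voltage
    thresholds and spike delays from proximal geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
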