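Package: lfpattractor
Title: Nonlinear Time-Series Analysis of Stimulus-Evoked Local Field
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting nonlinearity and reconstructing
    low-dimensional attractors from trial ensembles of local field
    potential (LFP) recordings evoked by brief periodic stimulation.
    Provides surrogate-data nonlinearity tests (Fourier-transform, AAFT
    and IAAFT surrogates; time-reversal asymmetry and false nearest
    neighbour discriminating statistics), correction of stimulus-induced
    phase resetting by circular shifting, dendrogram-based grouping of
    trials, delay-embedding parameter selection (autocorrelation first
    zero, average mutual information first minimum, false nearest
    neighbours with a Theiler window), and a Morris-Lecar based synthetic
    LFP generator with known ground truth for validating the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
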