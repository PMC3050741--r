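Package: kinetred
Title: Identifiability-Guided Reduction of Kinetic Reaction-Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative, identifiability-guided simplification of mass-action
    ODE models of signalling pathways. Provides a declarative reaction-network
    representation, stiff integration of the state and forward-sensitivity
    equations under pulse stimulation, multi-start maximum-likelihood parameter
    estimation in log-parameter space with Latin Hypercube start sampling, an
    eigenvalue-based identifiability ranking built on the Gauss-Newton Hessian,
    a variance-based identifiability verdict from accepted multi-start
    estimates, and small-sample Akaike (AICc) model comparison. Ships a
    reconstructed early JAK-STAT signalling model family as a worked example of
    the reduction workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'network.R'
    'simulate.R'
    'design.R'
    'estimation.R'
    'identifiability.R'
    'variance.R'
    'selection.R'
    'workflow.R'
    'cli.R'
    'jakstat.R'
    'kinetred-package.R'
    'modelio.R'
    'utils.R'
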