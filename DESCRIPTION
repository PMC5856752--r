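Package: flowcircuit
Title: Function-Specific Brain Circuits from Joint Structural-Functional
    Network Flow Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint modeling of diffusion-MRI structural connectivity and
    fMRI-derived functional activation as a network flow problem. A linear
    program distributes information flow over a structural connectome under
    link-capacity, node-demand and feasibility constraints, yielding
    function-specific anatomical circuits per functional mode and nonnegative
    capacity corrections that recover structural connections under-estimated
    by tractography. Includes a synthetic Fibercup-like phantom with
    SimTB-style BOLD simulation (block design, double-gamma hemodynamic
    response, Rician noise), tractography error emulation, FastICA source
    separation, and a six-component joint Gaussian-mixture baseline fit by
    expectation maximization. The linear programs are solved with a dense
    two-phase primal simplex implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'flow-model.R'
    'connectivity.R'
    'phantom.R'
    'gmm.R'
    'io.R'
    'cli.R'
    'flowcircuit-package.R'
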