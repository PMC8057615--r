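Package: csfgrn
Title: Kinetic Modelling of a CSF1R-Centered Pro-Inflammatory Gene Regulatory Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of an 11-component pro-inflammatory gene
    regulatory network centered on the colony stimulating factor 1 receptor
    (CSF1R), with tools for the full in-silico experiment suite around it:
    stiff integration of LPS step, washout and knockdown protocols;
    fold-change perturbation screens; multi-start steady-state analysis,
    pseudo-arclength continuation and saddle-node location demonstrating
    irreversible bistability; heterogeneous cell-population ensembles with
    uniform random parameter variation; least-squares calibration to
    qPCR-style mRNA time courses; and a synthetic qPCR data generator for
    parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
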