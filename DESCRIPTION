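Package: hsqcscreen
Title: Protein-Observed NMR Fragment Screening and Chemical Shift
    Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of protein-observed 2D 1H-15N HSQC
    fragment screens against a small chemokine target. Provides peak-list
    and gridded-spectrum data structures with Sparky-style I/O, synthetic
    screening data with fast-exchange peak movement under single-site
    binding with ligand depletion, pooled-library triage by difference
    intensity analysis (DIA) with PCA and k-means clustering, iterative
    plex deconvolution, combined 1H/15N chemical shift perturbation (CSP)
    mapping with significance thresholds and binding-site assignment,
    dissociation-constant fitting from titration series, binding-mode
    classification, and dual-fragment titration analysis of shift-vector
    additivity for simultaneous sub-site binding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
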