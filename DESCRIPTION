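Package: lcpipe
Title: Structural and Functional Quantification of the Locus Coeruleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for structural-functional
    studies of the locus coeruleus (LC). Quantifies LC structural integrity
    from neuromelanin-sensitive-like volumes via slice-wise, pons-normalized
    contrast on a skeletonized LC mask; quantifies the LC functional response
    to auditory oddball targets with an event-related general linear model
    (canonical HRF, discrete-cosine high-pass, motion and cardiac/respiratory
    Fourier nuisance regressors, small-volume correction); and relates the
    two with multivariate linear models and a minimum-detectable-effect
    sensitivity analysis. Includes a synthetic-data module that generates
    cohorts, LC phantoms, rater masks, oddball designs, physiological traces
    and BOLD series with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
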