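Package: numddm
Title: Drift-Diffusion Modelling of Numeral Comparison and Choice Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting, and confidence analysis of a
    drift-diffusion model (DDM) of single-digit numeral comparison. Drift rates are
    compressed by logarithmic numerical distance, choices arise from a noisy
    accumulator with symmetric absorbing bounds, and trial-level confidence is a
    Bayesian posterior probability of being correct evaluated at the moment of
    choice. Includes the experimental trial designs, a Crank-Nicolson first-passage
    time solver used as the likelihood backbone, seeded differential-evolution
    fitting per participant and numeral type, theory-based confidence-signature
    diagnostics (accuracy by confidence bin, correct-versus-error confidence,
    within-subject median splits), and a synthetic-cohort generator with a noisy
    confidence-to-button-pressure transfer for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
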