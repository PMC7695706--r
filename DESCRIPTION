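Package: famix
Title: Bayesian Diet Estimation from Fatty-Acid Signatures with
    Calibration Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates diet composition of consumers from proportional
    fatty-acid (FA) signatures using a Bayesian mixing model with
    multiplicative trophic modification. Sources are taken to "predator
    space" by per-FA calibration coefficients (CCs), tracers enter a
    normal likelihood with Residual*Process variance, and diet
    proportions receive Dirichlet priors (non-informative or
    informative), optionally per level of a fixed factor. Includes the
    standard data-preparation rules for FA tracers (abundance, dietary
    class and CC filters), PERMANOVA-based source-separation testing, a
    synthetic feeding-trial generator with diet switches, incomplete
    turnover and reduced lipid deposition, and recovery diagnostics
    against known diets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
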