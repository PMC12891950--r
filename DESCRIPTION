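Package: apdecon
Title: Deconvolution of Ischemic Drivers from Cardiac Action Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ventricular cardiomyocyte action potentials under
    graded ischemia (hyperkalemia, intracellular acidosis, and ATP-sensitive
    potassium current activation) in two ionic models -- the Luo-Rudy 1991
    guinea-pig ventricular model and the ten Tusscher 2006 human epicardial
    model -- extracts six waveform biomarkers, and trains a pair of random
    forest regressors that recover the underlying extracellular potassium
    concentration and intracellular pH from a single action potential.
    Includes cross-model validation of the learned mapping and a simulated
    pharmacological rescue experiment (complete IK(ATP) block).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    ranger,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
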