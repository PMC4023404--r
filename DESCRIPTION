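Package: erkshuttle
Title: Kinetics of ERK Phosphorylation, Nucleocytoplasmic Shuttling, and
    Substrate Buffering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmental kinetic modeling of the MEK-ERK cascade with
    negative feedback, nucleocytoplasmic shuttling, and anchoring of active
    ERK by cytosolic and nuclear substrates. Simulates stimulation and
    inhibitor protocols, maps trajectories to immunoblot, mass-spectrometry,
    nuclear-localization and FRET-reporter readouts, generates synthetic
    replicate datasets, fits parameter-set ensembles by simulated annealing
    with threshold acceptance, and analyzes substrate buffering strengths and
    inhibition-timing predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
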