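Package: laidepot
Title: Muscle-Compartment Simulation of Long-Acting Injectable Nanocrystal Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-mechanistic pharmacokinetic simulation of intramuscular
    long-acting injectable nanocrystal suspensions. A measured particle-size
    distribution is split into mass-percentile bins; each bin dissolves by
    diffusion-layer (Nernst-Brunner) kinetics after a fitted lag time into a
    small depot volume, from which perfusion carries drug into a
    one-compartment disposition model. Includes non-compartmental analysis of
    concentration-time curves, blood-flow-based dog-to-human parameter
    scaling, bound-constrained estimation of per-bin lag times from observed
    data, and virtual-population simulation with percentile bands and
    geometric-mean exposure summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
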