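Package: tumorcord
Title: Tumor-Cord Drug Transport Simulation and Boolean Mechanism Inference
    for Electro-Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the systemic delivery of a chemotherapeutic drug
    (doxorubicin) into an axisymmetric tumor cord surrounding a single
    capillary, coupling extracellular, free-intracellular and
    bound-intracellular concentration fields to a one-dimensional
    bloodstream advection model with a leaky porous vessel wall.
    Reversible electroporation enters through field- and time-dependent
    membrane and vessel-wall permeabilities, a vasoconstriction law for
    the vessel radius, and the induced radial tissue motion.  Two inlet
    pharmacokinetic profiles (one-short tri-exponential and
    mono-exponential bolus) are provided.  A Boolean logical-inference
    engine classifies, point by point and interval by interval, which
    reaction and transport mechanisms (internalization, externalization,
    association, dissociation, extracellular transport) are present and
    how their rates are ordered, with an exhaustive truth-table verifier
    for the underlying scenario table.  Post-processing utilities report
    concentration ratios, radial and axial uniformity ranges,
    transvascular ratios, reverse-diffusion crossing times and exposure
    integrals as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
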