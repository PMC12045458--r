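Package: bcear
Title: Lumped-Element Middle-Ear Mechanics for Bone-Conduction Hearing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the vibration of the human middle ear under
    bone-conduction (skull-borne) and air-conduction stimulation with a
    six-node lumped-element mechanical model: skull, ear-canal air,
    tympanic membrane, malleus and incus (as hinged pendulums), and the
    stapes plus cochlear fluid. Assembles the mass, damping and stiffness
    matrices from built-in or user-supplied parameter sets, solves the
    harmonic response over a frequency grid, applies virtual experimental
    perturbations (ossicle gluing, mass loading, incudostapedial-joint
    separation, cochlea draining), and extracts umbo and stapes velocity
    transfer functions with their resonance and crossover features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
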