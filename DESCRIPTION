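Package: t4sim
Title: Passive-Membrane Motion Detector Simulation for Fly T4 Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator of a conductance-based model of direction
    selectivity in fly T4 neurons, in which preferred direction
    enhancement arises from release of shunting inhibition in a purely
    passive dendrite. Provides the closed-form algebra of the passive
    equivalent circuit (sublinear summation of two excitatory inputs,
    supralinear interaction of excitation with disinhibition), synthetic
    visual stimuli (drifting sine gratings, Poisson photon noise,
    random-dot kinematograms), the peripheral filter stages and the
    retinotopic three-input detector array with its partial variants,
    and the tuning and signal-to-noise analyses that characterise the
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
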