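Package: synstim
Title: Synergy-Driven Electrical Stimulation Simulator for Balance Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for muscle-synergy-based balance training with
    functional electrical stimulation (FES). Extracts muscle synergies from EMG
    envelope matrices by nonnegative matrix factorization, builds a cycle-locked
    neural-command table from a sinusoidal center-of-pressure sway reference,
    drives a simulated 32-channel electrostimulator through the synergy model
    M = H x W x Imax, models a four-sensor force plate, and validates the chain
    with timing-tolerance analysis of synergy-update periods and low-pass
    reconstruction of the stimulated EMG envelope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
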