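Package: cpgrhythm
Title: Analytical Half-Center Oscillator Model of Locomotor Rhythm and Steering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form and simulated dynamics of a single-limb central pattern
    generator modelled as two reciprocal leaky integrators with threshold
    resetting. Provides exact and Taylor-approximation solutions for locomotor
    phase and step-cycle durations as a function of a limb-speed drive, an
    event-detecting time-domain simulator, validation of the analytical cycle
    duration against the phenomenological speed-duration power law of cat
    walking, and a two-limb differential-drive steering model for
    heading-direction control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
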