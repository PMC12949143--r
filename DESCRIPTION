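Package: rebreathe
Title: Two-Breath CO2 Rebreathing Estimation of Effective Lung Volume
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bedside estimation of effective lung volume (ELV) and functional
    residual capacity (FRC) from CO2 rebreathing capnograms. Segments
    sidestream capnometer traces into breaths, extracts end-tidal CO2, and
    applies a two-breath weighted estimator (ELV = 2 * avPet * DV /
    (dPet1 + w * dPet2), FRC = K * ELV) with quality-control gating for
    irregular breathing, mouthpiece leakage and dead-space-to-tidal-volume
    ratio. Includes a physiologically grounded rebreathing capnogram
    simulator with known ground truth (exponential end-tidal wash-in,
    analyzer lag, transport delay, noise, artifact injection), Bland-Altman
    method-agreement statistics with percentage error and the
    exchangeability criterion, and an alveolar sphere-layer geometry
    consistency check for the FRC/ELV proportionality constant.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    zoo,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
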