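Package: rnlcolour
Title: Receptor-Noise-Limited Colour Discrimination Under Background Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models tetrachromatic (avian) colour discrimination with the
    receptor-noise-limited (RNL) model under von Kries adaptation to a coloured
    background. Builds cone spectral sensitivities from visual-pigment templates,
    oil-droplet cut-off filters and ocular media transmittance; computes quantum
    catches, chromaticities, receptor contrasts and just-noticeable-difference
    (JND) colour distances; fits logistic psychometric functions to
    two-alternative choice data by maximum likelihood with a binomially
    justified threshold criterion; and relates discrimination thresholds to
    stimulus-background contrast with a linear background-contrast correction,
    including the dipper-shaped detection regime. A synthetic-data module
    generates monitor-like stimulus spectra, saturation series, constrained
    reward schedules and simulated observers so the full analysis runs without
    live-animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
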