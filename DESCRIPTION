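Package: mesowin
Title: Mesoscopic Cranial-Window Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal mesoscopic imaging through
    transparent cranial windows in awake mice. Computes laser speckle
    contrast (K) maps and inverse-correlation-time (1/K^2) blood-flow
    indices, an Otsu-threshold vessel-area transparency statistic for
    intrinsic optical signal images, the interhemispheric homotopic
    functional-connectivity index (downsample, detrend, bandpass, global
    signal regression, mirrored-pixel correlation, Fisher z) with block
    analysis around cortical spreading depolarization, and microglia
    counting with Sholl ring-intersection profiles. Ships seeded synthetic
    generators (dynamic speckle, bilateral band-limited hemodynamics,
    vessel and occlusion fields, propagating flow transients, branched
    cell morphologies) so every stage is verifiable against known ground
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
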