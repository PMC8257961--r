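Package: beelek
Title: Analysis of Harmonic-Radar Insect Tracks and Aerial Lek Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing harmonic-radar tracks of flying insects,
    built around the study of honeybee drone congregation areas. Converts
    polar radar fixes to a local planar frame, filters substantial flight
    segments, classifies flight into straight and convoluted sections with
    a moving-window resultant-vector-length algorithm, discovers candidate
    congregation areas (aerial leks) by single-linkage clustering of
    convoluted-flight fixes, quantifies swarm cohesion via acceleration
    versus position regressions, binned acceleration profiles, kurtosis
    and normal-probability diagnostics, counts multi-lek visits, and
    renders landscape occupancy heat maps from a timesliced Brownian
    bridge model. A synthetic track simulator with known ground truth
    (commuting legs, potential-well swarming, radar sampling artefacts)
    makes every pipeline stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
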