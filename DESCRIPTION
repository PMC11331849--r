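Package: octcaliper
Title: Simulating Calliper Measurement Error for Macular Holes on OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of manual calliper measurement error for
    full-thickness macular holes (FTMH) on optical coherence tomography
    (OCT). Models the discrete b-scan raster sampling of a circular hole
    aperture (chord geometry and the worst-case apparent-size formula),
    resolution-dependent observer reference-point jitter and systematic
    bias, slice-selection error, and vertical display-scaling induced
    oblique height measurements. Generates seeded synthetic cohorts
    emulating a two-machine, two-observer reading study, and analyses
    agreement with Bland-Altman limits of agreement and the two-way
    absolute-agreement intraclass correlation coefficient ICC(A,1)
    computed from ANOVA mean squares with F-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
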