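Package: rumpalm
Title: Single-Molecule Localization Simulation and Analysis of the Chytrid Rumposome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of photoactivated localization
    microscopy (PALM) experiments on the natively fluorescent, bistable
    photoreceptor NeoR in chytrid zoospores. Simulates photoswitching EMCCD
    movies of emitters arranged on a hexagonal lattice inside a crescent
    rumposome band, performs spot detection and Poisson maximum-likelihood
    Gaussian fitting with Thompson precision estimates, corrects lateral
    drift by temporal-block image cross-correlation, counts molecules from
    merged blink events, detects lattice periodicity in intensity profiles
    by rolling-ball background correction and spatial autocorrelation
    (including a rotated hexagonal-pattern projection analysis), and fits
    Hill-equation kinetics for rhodopsin guanylyl cyclase activity assays.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
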