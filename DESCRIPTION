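Package: mpsnorm
Title: Normal Stress Databases and Pixel-Wise Permutation Statistics for
    Myocardial Perfusion Polar Maps
Version: 0.1.0
Authors@R:
    person("MPS", "Maintainers", email = "mpsnorm@example.org",
           role = c("aut", "cre"))
Description: Builds pixel-wise normal stress databases from myocardial
    perfusion SPECT polar maps (65x65 bull's eye count grids), compares
    them with pixel-wise t-statistics corrected for multiplicity by the
    max-|t| permutation procedure (strong family-wise error control), and
    summarises group differences per anatomical segment on a normalized
    -100..100 count scale.  Includes a synthetic cohort generator that
    emulates gender- and BMI-dependent attenuation artifacts in paired
    non-corrected/attenuation-corrected map pairs, count normalization to
    the median of the brightest ten percent of pixels, CSV-based map and
    cohort interchange formats, a study-replication command line driver,
    and bull's eye rendering with significance overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
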