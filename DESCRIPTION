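Package: seasonwood
Title: Reconstruction of Insect Defoliation Events from Seasonal Tree-Ring Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing past late-summer and autumn insect
    defoliation events from earlywood and latewood ring-width series of host
    trees. Implements the pointer-year method, which dates defoliation from a
    synchronous latewood growth decline one year after damage followed by an
    earlywood decline in the second year, together with three reference
    detectors operating on total ring width (sustained-suppression OUTBREAK
    screening, moving-window local minima, and independent-component
    decomposition), grid-search calibration of detector parameters against
    documented outbreak records, lag-tolerant concordance statistics with
    Fisher's exact test and Benjamini-Yekutieli correction, and linear
    climate-versus-defoliation modelling with bootstrap comparison and
    superposed epoch analysis. Includes readers and writers for Tucson (RWL)
    decadal measurement files and seasonal ring-width tables, chronology
    construction and quality statistics (EPS, SNR), and a seed-reproducible
    generator of synthetic multi-tree seasonal ring-width data with known
    defoliation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
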