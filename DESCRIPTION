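Package: mapsrts
Title: Scoring, Reliability and Route Sampling for the MAPS-SRTS School
    Streetscape Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the Micro-scale Audit of Pedestrian Streetscapes for
    Safe Routes to School (MAPS-SRTS) observational instrument. Ships a
    machine-readable scoring dictionary (90 items over school access segments,
    other segments near school, and crossings), computes the hierarchical
    positive/negative valence subscale, section-overall and total scores,
    estimates one-way random-effects single-measure intraclass correlation
    coefficients with exact F-based confidence intervals, applies the
    subscale retention decision rules used to revise the instrument, samples
    nearest-neighbor observation routes from street-network graphs, and
    generates synthetic paired-rater audit data with calibrated agreement for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
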