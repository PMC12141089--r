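Package: gridShift
Title: Range Boundary and Centroid Shift Trends from Checklist Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates breeding-range boundary and centroid shifts from
    semi-structured community-science checklist data (eBird Basic Dataset
    style tables). Provides zero-filling of sampling events, checklist
    quality filtering, equal-area 10 km gridding with a minimum-years cell
    retention rule, per-region annual detection and effort range metrics
    (union centroids and bounding-box limits), and effort-corrected ordinary
    least squares trend estimation with degree-to-kilometre conversion.
    Includes a synthetic checklist generator with known occupancy and
    observer-effort drift so the full pipeline is testable against ground
    truth without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    mgcv,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
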