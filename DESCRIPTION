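Package: specimargin
Title: Digital Specimens for Volumetric Resection-Margin Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional digital specimens of surgical resection
    specimens from labeled volumes, partitions their outer surface into the
    five conventional anatomical margin regions (anterior, posterior,
    craniomedial, caudolateral, deep central), maps tumor-to-surface margin
    distances against the 5 mm adequacy threshold, emulates conventional
    slice-based histopathological margin assessment, reconstructs volumes
    from registered serial sections, and quantifies observer agreement with
    under- and overestimation 95th-percentile Hausdorff distances and
    diagnostic-accuracy statistics with exact binomial confidence intervals.
    Includes a synthetic phantom generator with known ground-truth margins
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    RANN,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
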