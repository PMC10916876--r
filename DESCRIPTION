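Package: biomorph
Title: Biologically Annotated Feature Spaces for Morphological Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a biologically annotated feature space ("BioMorph
    terms") from paired image-based morphological profiles and cell-health
    readouts, transforms new profiles into that space via a group-level
    chi-squared statistic, trains and evaluates activity classifiers with
    repeated nested cross-validation and Youden-J thresholding, and maps
    model importances and per-compound attributions into multi-level term
    enrichments for mechanism-of-action interpretation. Includes an
    all-relevant shadow-feature selection procedure, a synthetic-data
    generator with planted structure for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0),
    arrow,
    pROC,
    withr
Config/testthat/edition: 3
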