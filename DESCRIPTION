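Package: diffcornet
Title: Differential Correlation Network Analysis for Two-Group Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies metabolite pairs whose Pearson correlation differs
    between two phenotype groups (e.g. responders and non-responders to
    total joint replacement), using a Fisher z-based differential
    correlation statistic that accounts for unequal group sizes,
    label-shuffling permutation tests, and signed network construction.
    Includes metabolomics quality control (limit-of-detection filtering,
    mean imputation, log/Z-score normalization, outlier masking),
    WOMAC-based responder classification using minimal clinically
    important differences, and a synthetic cohort generator with planted
    differential correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
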