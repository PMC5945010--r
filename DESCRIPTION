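Package: phenogreen
Title: Vegetation Phenology from Crowdsourced Image Greenness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate seasonal vegetation cycles (phenology) from
    large, noisy corpora of crowdsourced photographs. Computes a per-image
    green chromatic coordinate (mean of G/(R+G+B) over pixels), applies
    corpus-cleaning filters for duplicate and undersized files, aggregates
    to monthly and seasonal park-level means with percentile-bootstrap
    confidence intervals, and compares the resulting cycles against a
    gridded monthly NDVI product via pooled Pearson and Spearman
    correlation with bootstrap uncertainty. Includes a synthetic corpus
    and NDVI-grid generator with known ground truth for end-to-end
    validation, plus a pipeline orchestrating simulate, analyze and
    report stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
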