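Package: efnmosaic
Title: Geographic-Mosaic Analysis of Ant-Plant-Herbivore Interactions Mediated by Extrafloral Nectaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing geographic mosaics of facultative ant-plant
    protection mutualisms mediated by extrafloral nectaries (EFNs). Computes
    proportional (Steinhaus) similarity of ant and herbivore assemblages with
    bootstrap confidence limits, dissimilarity and great-circle distance
    matrices with Mantel permutation tests, species-level functional ant
    traits (body size, recruitment) and community-weighted trait means,
    per-plant herbivory and performance descriptors with one-way ANOVA,
    Tukey letter displays and Fligner-Killeen variance comparisons,
    cross-species phenotype-function regressions with jackknife inference and
    mean-response confidence bands, and a band-based classifier of
    phenotypically matched, mismatched and evolutionary-hotspot populations.
    Includes a synthetic multi-population survey generator with known
    ground-truth labels so every stage of the pipeline can be tested without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
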