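Package: bsarank
Title: Scoring and Ranking of Broad-Spectrum Antivirals and Their Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-driven prioritization of broad-spectrum antiviral (BSA)
    monotherapies and two-drug BSA-containing combinations (BCCs) for pandemic
    preparedness. Implements a six-component additive BSA score (structural
    identity or similarity, development status, target relevance,
    immunomodulation, route-of-administration suitability, and phylogenetic
    proximity of the virus of interest) and a four-coefficient multiplicative
    combination score with an effectiveness rule, together with the supporting
    machinery: ECFP4-style circular fingerprints with Tanimoto similarity and
    average-linkage sub-cluster extraction for candidate nomination,
    taxonomy-based virus relatedness, activity-gap prediction across related
    viruses, tabular annotation readers and writers, packaged worked-example
    fixtures, and a seeded synthetic annotation-bundle generator for property
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
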