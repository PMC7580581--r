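Package: scentR
Title: Multivariate Analysis of GC-MS Chemical Fingerprints with Colony
    and Family Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing aligned gas chromatography-mass
    spectrometry (GC-MS) peak tables from skin-swab chemical fingerprints
    of group-living animals. Implements the statistical pipeline used to
    test for chemical signatures of breeding-colony membership and
    mother-offspring similarity: preprocessing of aligned peak tables
    (rare-compound exclusion, relative-abundance normalisation, log(x+1)
    transformation), Bray-Curtis dissimilarities, sequential (Type I)
    PERMANOVA with nested family-within-colony terms and permutation null
    distributions, tests for multivariate homogeneity of group
    dispersions, pairwise PERMANOVAs with Bonferroni correction,
    non-metric multidimensional scaling, and a bootstrap-over-families
    standardisation of PERMANOVA R-squared effect sizes that makes effect
    magnitudes comparable across studies with different sample sizes. A
    seeded synthetic-data generator with colony-, family- and
    individual-level variance components supports power analysis and
    end-to-end testing without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS
Config/testthat/edition: 3
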