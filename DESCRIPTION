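Package: fosterbiome
Title: Cloacal Microbiota Dynamics Under Partial Cross-Fostering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-clustering analysis of 16S OTU tables from a partial
    cross-fostering experiment on nestling birds sampled at two ages.
    Implements the full decontamination and filtering cascade (PCR-replicate
    averaging, mistag blank subtraction, negative-control contaminant
    detection, low-abundance filtering, rarefaction), alpha diversity and
    presence-absence Jaccard beta diversity, from-scratch permutation
    statistics (Mantel, marginal PERMANOVA, PCoA, distance-to-centroid
    dispersion), standardized major axis regression and the scaled mass
    index, random-intercept mixed models for the design-specific contrasts,
    and a Dirichlet-multinomial synthetic-data generator that emulates the
    nest-structured, cross-fostered sampling design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
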