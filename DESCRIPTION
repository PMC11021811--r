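Package: bonephen
Title: Multi-Scale Cortical Bone Phenomics for Inbred Founder and Diversity
    Outbred Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale analysis of cortical bone traits across
    inbred mouse strain panels and Diversity Outbred (DO) cohorts: extraction
    of whole-bone mechanical properties (stiffness, yield and ultimate force,
    post-yield displacement, work-to-fracture) from three-point bending
    force-displacement curves with beam-theory material-property estimates;
    broad-sense heritability from two-factor (strain x sex) ANOVA variance
    components; per-strain allometric body-mass adjustment with slope
    zeroing; Pearson trait correlation matrices with significance masking and
    Ward.D2 trait clustering; principal component analysis fitted on founder
    strains with projection of outbred animals into the founder PC space; and
    Raman bone-matrix compositional metrics (mineral to matrix and carbonate
    to phosphate band-area ratios, crystallinity) with iterative polynomial
    baseline subtraction. A synthetic-cohort generator emulating the
    8-founder-strain plus DO study design provides ground-truth data for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    minpack.lm,
    pracma,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
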