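Package: periplaque
Title: Perivascular Amyloid Plaque Topography in Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the topographic distribution of hyperfluorescent
    amyloid plaques relative to the retinal vasculature in fundus
    fluorescence images. Provides a vessel branch-order taxonomy
    (primary/secondary/tertiary, main versus small protruding branches),
    diameter-scaled perivascular band construction (one vessel diameter on
    either side of the traced centerline), plaque spot detection and
    border-touch zone assignment, stratified per-subject count tables, and a
    cohort statistics layer with normality-gated test selection, fold
    changes with Fieller confidence intervals, one-way ANOVA with Tukey
    post-hoc comparisons, and Pearson correlation tables with
    Holm-Bonferroni flags. Includes seeded synthetic-data generators for
    vascular trees, rendered fluorescence images with planted plaques, and
    cohort count/metadata tables, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
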