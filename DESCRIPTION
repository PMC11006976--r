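Package: seedtol
Title: Seed Germination Stress-Tolerance Indices and Trait-Environment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes weighted seed germination stress-tolerance indices
    (drought, cold and saline-alkali) from daily germination counts under
    graded treatment levels, and carries the indices through the downstream
    analyses used in plant trait-biogeography studies: per-trait variation
    summaries with one-way ANOVA, simple linear regressions along geographic
    gradients, standardized multiple regressions on climate and soil
    predictors, random-intercept linear mixed models fitted by profile REML
    with block-wise effect decomposition, and a recursive path model over
    PCA block composites with maximum-likelihood fit indices. A synthetic
    data generator emulates the sampling design (sites, traits and dish-level
    germination time series) so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), lme4, lmerTest, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
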