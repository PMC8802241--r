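Package: hybridmismatch
Title: Multivariate Trait Mismatch in Hybrids Between Divergent Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies multivariate phenotypic divergence between parent
    populations and the perpendicular "mismatch" of hybrid phenotypes
    relative to the line joining the two parental mean phenotypes.
    Provides size correction of linear measurements, fixation-position
    correction and z-standardization; decomposition of mean hybrid
    mismatch into dominance and variance components; per-trait
    additive/dominance line-cross models with family random effects;
    divergence-mismatch regressions and a "snowball" analysis of
    significantly mismatched trait pairs; and a synthetic cross
    generator with a recorded ground truth for end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
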