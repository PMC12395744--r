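Package: prsscreen
Title: Polygenic Risk Scores for Risk-Stratified Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an ancestry-tailored polygenic risk score (PRS) engine
    with Hardy-Weinberg mean-relative-risk centering, a configuration-driven
    5-year absolute breast cancer risk projection in the style of the Breast
    Cancer Surveillance Consortium (BCSC) model, a Bayesian odds-update
    combination of the two, and a threshold-table screening-policy engine.
    An analysis layer cross-tabulates screening recommendations under the
    clinical model alone versus the PRS-modified model, computes discordance
    and screening-utilization summaries, exports Sankey flows, and provides
    rank-based group comparisons including a Jonckheere-Terpstra trend test.
    A synthetic cohort generator emulates the demographic composition,
    Hardy-Weinberg genotypes, and PRS-phenotype gradients of a risk-based
    screening trial population so the full pipeline is testable without
    access to individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
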