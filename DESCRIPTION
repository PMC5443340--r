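Package: embryoloss
Title: Quantitative Re-Evaluation of Natural Human Embryo Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative assessment of natural human embryo
    mortality. Implements a conditional-probability decomposition of
    per-cycle reproductive success (fecundability) into sperm-ovum
    co-localisation, fertilisation, implantation, clinical recognition and
    live birth; the Roberts & Lowe conception ledger with deterministic
    scenario adjustment and Monte Carlo sensitivity analysis; a
    staggered-entry actuarial life table for gestational pregnancy loss;
    the Hertig embryo-loss derivation with balanced-bootstrap percentile
    confidence intervals and exact (Clopper-Pearson) and approximate
    (Agresti-Coull) binomial intervals; summary statistics over thirteen
    prospective hCG early-pregnancy studies; and seeded generators for
    synthetic hCG cohorts and cross-sectional embryo-collection studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
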