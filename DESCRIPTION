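Package: gxeortho
Title: Orthogonality Assessment for Polygenic Gene-Environment Interaction Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether an environmental exposure is orthogonal to
    the genetic propensity for an outcome before fitting polygenic-index (PGI)
    by environment interaction models. Implements the PGI-distribution test
    battery (t test, conditional correlation, Kolmogorov-Smirnov), SNP-based
    heritability and bivariate genetic-correlation estimation by average
    information restricted maximum likelihood (AI-REML) on a genetic
    relatedness matrix, a likelihood-ratio test of zero genetic correlation,
    and a four-quadrant interpretation of the two test families. A seeded
    forward simulator generates cohort pairs whose gene-environment
    correlation structure makes the two families agree or disagree
    (exogenous assignment, genetic selection, hidden genetic overlap,
    population-structure confounding), together with GWAS weight estimation,
    PGI construction, relatedness pruning, Keller-robust G-by-E regressions,
    and an end-to-end scenario study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
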