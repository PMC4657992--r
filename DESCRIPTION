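Package: twinsem
Title: Multivariate Variance-Component Structural Equation Models for Twin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical twin-design analysis of mixed continuous and binary
    phenotypes. Decomposes phenotypic variance and covariance into additive
    genetic (A), shared environmental (C), dominance (D) and non-shared
    environmental (E) components with Cholesky, independent-pathway and
    common-pathway structural models fitted by full-information maximum
    likelihood on monozygotic/dizygotic twin-pair data, handling missing
    co-twins and liability-threshold binary traits. Includes a synthetic
    twin-cohort generator, phenotypic and cross-twin cross-trait correlation
    estimators (Pearson, tetrachoric, biserial), a likelihood-ratio/AIC model
    comparison ladder, and variance-decomposition reports (heritability,
    genetic and environmental correlations, shared-genetic-variance
    attribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    numDeriv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
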