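Package: covfdr
Title: Covariate-Adaptive False Discovery Rate Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Large-scale multiple hypothesis testing that uses per-hypothesis
    covariates to learn an adaptive p-value rejection threshold, modelled as a
    generalized linear term plus Gaussian bumps. False discoveries are
    estimated with a mirror estimator and the false discovery proportion is
    controlled via two-fold cross-fitting with a rescale search. Includes an
    EM-only fast variant, Benjamini-Hochberg and Storey baselines, covariate
    diagnostics, and a seeded synthetic-data generator with configurable
    dependence among null p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
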