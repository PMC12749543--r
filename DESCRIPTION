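Package: longchange
Title: Longitudinal Brain-Change and Memory-Change Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual differences in structural brain
    change relate to episodic memory change in multi-cohort longitudinal aging
    studies. Provides a synthetic multi-site cohort generator with skew-normal
    latent decline, preprocessing (baseline z-scoring, PCA memory composites
    with low-rank imputation, GAMM-based age/sex/site deviation scores),
    per-subject yearly change scores with growth-rate-reliability weights,
    weighted penalized-spline association models with tensor age interactions,
    density-weighted effect sizes over the declining range, wild-bootstrap
    inference with FDR correction, Monte-Carlo reference consensus clustering
    of regional change, and a two-source measurement-error simulation that
    reproduces the nonlinear change-change association pattern.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
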