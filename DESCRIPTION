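Package: spatccc
Title: Cell-Cell Communication Inference from Spatially Resolved
    Transcriptomics with Tweedie Generalized Additive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed cell-cell communication from spatially
    resolved transcriptomics (single-cell resolution or spot-based) by
    regressing pairwise ligand-receptor communication scores on
    distance-decayed cell-type interaction covariates under a compound
    Poisson-Gamma (Tweedie) generalized additive model with
    ridge-penalized sender and receiver grid random effects. Provides
    penalized IRLS fitting with GCV smoothing selection, AIC-based
    distance-decay selection, Wald inference with BH false discovery
    rate control, pathway-level aggregation, a synthetic-data generator
    with planted communication structure, heatmap and network
    visualizations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
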