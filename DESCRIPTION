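Package: decaywood
Title: Microbial Community Succession and Assembly in Decaying Wood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for bacterial and fungal community
    succession along a wood-decay gradient: rarefaction and alpha
    diversity (Chao1, Shannon) with diversity-versus-density regressions,
    decay-stage partitioning by a multivariate regression tree on
    Bray-Curtis dissimilarity, Metastats-style permutation tests for
    differential abundance with FDR control, genus-level Pearson
    co-occurrence networks, and classification of community assembly as
    neutral or niche-based by fitting rank abundance distributions to
    five niche models and the zero-sum multinomial (Etienne sampling
    formula), compared via AIC and Akaike weights. Includes a synthetic
    decay-study generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
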