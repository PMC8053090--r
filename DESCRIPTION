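Package: uvrdh
Title: Quantification of UV-Induced Pyrimidine Dimers and RNA:DNA Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gel- and blot-based quantification of
    UV-induced pyrimidine dimers (PDs) and RNA:DNA hybrids (RDHs) in
    bacterial DNA. Implements Poisson zero-class lesion density estimation
    from plasmid relaxation assays, western/southern blot densitometry with
    batch normalization, the 16-fraction gel-lane co-enrichment statistic,
    DRIP (DNA:RNA immunoprecipitation) enrichment ratios with a theoretical
    anchored-PD co-occurrence model, UV survival curves with multiplicative
    epistasis prediction, and DNA synthesis rate recovery curves. A
    scenario-driven synthetic data generator emulates each assay so every
    stage of the pipeline is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
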