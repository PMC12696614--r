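Package: vegdry
Title: Vegetation Browning, Hydro-Climatic Drying, and Driver Attribution on Gridded Annual Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and attribute vegetation browning that coincides
    with multi-variable drying on gridded annual time series. Provides
    Mann-Kendall trend tests with Theil-Sen slopes, a permutation bootstrap
    for period-mean changes, derived water-demand variables (vapor pressure
    deficit from the Magnus equations, a radiation-over-precipitation dryness
    index), drying-agreement and browning coincidence maps with
    latitude-weighted area statistics and Cramer's V correspondence, per-cell
    driver attribution of inter-annual leaf area index dynamics via
    all-subsets regression with AIC ensembles, Lindeman-Merenda-Gold variance
    partitioning and Akaike weighting, multi-model ensemble voting summaries,
    and a synthetic gridded-data generator with known trends, AR(1) noise and
    driver coupling for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
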