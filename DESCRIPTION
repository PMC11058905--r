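Package: rhizcensus
Title: Global Census of Rhizaria Carbon and Biogenic Silica Stocks from In Situ Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts in-situ imaged Rhizaria objects (Underwater Vision
    Profiler 5 exports) into organic-carbon and biogenic-silica standing
    stocks, temperature-dependent carbon demand and silica production,
    aggregates them onto a 1-degree global grid matched to environmental
    climatologies, fits boosted regression trees with random and spatial
    block cross-validation to map concentrations globally, and integrates
    the maps into layer, regional and global element budgets including
    particulate-organic-carbon flux-attenuation ratios. Ships a synthetic
    world generator with a known environment-to-biomass response so the
    whole pipeline can be exercised and validated without any external
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
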