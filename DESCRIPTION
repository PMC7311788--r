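Package: nichetable
Title: Trait-Based Periodic Tables of Plant Functional Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds continuous "periodic table of niches" ordinations for
    woody plant communities from eleven functional traits grouped into three
    niche dimensions (leaf economy, mechanical support, reproductive
    phenology). Derives leaf, stem, size-percentile and Julian-date phenology
    traits from raw measurements; ordinates species with a nested
    PCA-of-PCAs; quantifies niche periodicity as the family-to-species
    convergence ratio within fixed-width bins of niche space; and compares
    biomes with Kruskal-Wallis rank tests and compact letter displays. A
    latent-factor community simulator generates four-biome test communities
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
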