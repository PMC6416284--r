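Package: phosnet
Title: Phosphate-Source Effects on Soil Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the solubility of phosphate fertilizer
    sources (%P2O5), soil bacterial-fungal community structure, and sugarcane
    total dry matter. Takes DGGE band-intensity profiles through band-frequency
    filtering, Bray-Curtis ordination and PERMANOVA, dual Spearman/Pearson
    signed co-occurrence network inference with kingdom-partitioned topology
    reports (spinglass communities, modularity, degree and density under both
    published conventions), two-factor ANOVA with Tukey comparisons for plant
    phenotypes, and exponential dose-response fits composed into a prediction
    surface whose maximum locates the %P2O5 associated with the largest dry
    matter. Includes a synthetic-data generator with planted correlation
    structure so every stage is testable without the undeposited gel data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    minpack.lm,
    ape,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
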