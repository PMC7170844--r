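Package: microsucc
Title: Longitudinal Microbiome Succession Analysis for Dense 16S Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of longitudinal 16S rRNA OTU count tables from dense
    early-life sampling designs. Identifies core successional taxa by
    animal-level prevalence, quantifies species arrival and persistence
    against permutation null models, associates taxa with birth delivery
    mode via Dufrene-Legendre indicator species analysis, summarises taxon
    temporal placement by an abundance-weighted centre of mass, fits a
    temporal linear mixed model with a community-history kinship matrix to
    detect autoregressive taxa, and screens OTU tables for spurious taxa
    arising from sequencing error under a Poisson model. Includes a
    synthetic cohort generator with planted ground truth so every analysis
    stage has a recovery oracle, plus Bray-Curtis/PCoA/PERMANOVA community
    structure summaries built on vegan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    permute,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
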