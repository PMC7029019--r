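Package: ifomics
Title: Multi-Omics Integration Statistics for Intermittent-Fasting Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for two-group multi-omics studies linking
    gut microbiota, microbial metabolites and host gene expression.
    Provides compositional microbiome statistics (cumulative sum scaling,
    rarefaction, centered log-ratio transform, Bray-Curtis/PCoA ordination,
    PERMANOVA, partial constrained analysis of principal coordinates, ANCOM
    differential abundance), per-block PLS-DA under repeated double
    cross-validation with permutation testing, multi-block sparse
    discriminant integration (sparse generalized canonical correlation with
    exact per-block cardinality), a lean signed topological-overlap
    co-expression module and hub-gene workflow, and a synthetic multi-omics
    study generator with a shared latent factor so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    mclust
Config/testthat/edition: 3
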