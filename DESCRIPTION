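Package: hermetia
Title: Bioconversion Indices and Gut-Microbiome Statistics for Black
    Soldier Fly Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for black soldier fly (Hermetia illucens)
    larvae feeding trials on organic waste substrates. Computes the
    Waldbauer-family mass-budget bioconversion indices (growth rate,
    substrate reduction, consumption index, waste reduction index,
    approximate digestibility, and the efficiencies of conversion of
    ingested and digested food), multivariate analysis of substrate
    physicochemistry (PCA, k-means of variable loadings, hierarchical
    clustering, gap-statistic cluster-number selection), and 16S
    rRNA-amplicon community statistics: rarefaction, prevalence
    filtering, Shannon/Pielou alpha-diversity, Bray-Curtis
    dissimilarity, non-metric multidimensional scaling, PERMANOVA,
    Mantel tests, an indicator-species consensus of a linear
    discriminant effect-size screen with multi-level IndVal pattern
    analysis, and taxon-to-pathway functional projection. A synthetic
    trial generator with known ground truth makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
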