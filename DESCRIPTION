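Package: mesorefugia
Title: Refuge Potential of Mesophotic Reef-Fish Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether mesophotic reefs act as refuges for
    shallow reef-fish assemblages. Delimits the mesophotic zone from satellite
    water-turbidity series (Kd490 to KdPAR conversion and optical depths at
    10%, 1% and 0.1% surface light), builds transect-level community matrices
    from video-survey records, computes taxonomic, functional and phylogenetic
    diversity (convex-hull functional richness, originality and divergence;
    Hill numbers; abundance-weighted taxonomic distinctness with a permutation
    funnel), tests assemblage differences between depth strata with
    multivariate negative-binomial GLMs (PIT-trap resampling) and generalized
    linear mixed models, and classifies the refuge potential into five
    categories from "not refugia" to "enriched refugia". Includes a synthetic
    data generator emulating the survey structure so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    ape,
    jsonlite
Config/testthat/edition: 3
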