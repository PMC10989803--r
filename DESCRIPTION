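Package: commresist
Title: Community Resistance Potential from Tolerance Breadth and Response
    Asynchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the resistance potential of microbial communities
    surveyed along environmental gradients. Computes per-OTU environmental
    tolerance breadth as the abundance-weighted multivariate dispersion of
    occupied samples in standardized environment space, classifies putative
    habitat generalists and specialists by tolerance-breadth quantiles,
    quantifies pairwise response asynchrony as the negated Spearman
    correlation of relative-abundance profiles, and aggregates both to the
    community level (community mean tolerance breadth, CMTB, and community
    mean response asynchrony, CMRA) under abundance-based and fixed-richness
    OTU selection schemes. The two standardized indexes combine into a
    community resistance potential. Includes richness-gradient statistics
    (linear-versus-quadratic AIC model selection, Cohen's d, annual climate
    variation) and a Gaussian niche-model community simulator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
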