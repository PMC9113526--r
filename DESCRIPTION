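Package: ncmfit
Title: Neutral Community Model Analysis of Host-Associated Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the contribution of stochastic (neutral)
    processes to the assembly of host-associated bacterial communities
    from per-host 16S OTU count tables. Fits the Sloan neutral community
    model (beta-approximation of Hubbell dynamics) to occurrence
    frequencies and mean relative abundances, partitions taxa into
    above-, within- and below-neutral classes with Wilson score bands,
    and characterises community structure through alpha diversity,
    Bray-Curtis and Jaccard dissimilarities, principal coordinates
    analysis, PERMANOVA and ANOSIM. A discrete individual-based
    (Moran-type) neutral assembly simulator with known ground truth
    makes every stage of the analysis testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
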