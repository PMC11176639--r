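Package: ecoassembly
Title: Null-Model Quantification of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the ecological processes that assemble
    microbial communities from amplicon-style count tables, a rooted
    phylogeny and sample metadata. Implements the two-step phylogenetic
    null-model classification of pairwise community turnover (beta nearest
    taxon index and the Raup-Crick metric on Bray-Curtis dissimilarity)
    into homogeneous and heterogeneous selection, dispersal limitation,
    homogenizing dispersal and undominated turnover, together with the
    surrounding inference stack: depth filtering, rarefaction and
    cumulative sum scaling, collinearity pruning of soil covariates,
    alpha and beta diversity, principal coordinates, PERMANOVA, Mantel
    distance-decay, Procrustes congruence, distance-based forward
    selection of environmental predictors, Moran's eigenvector map
    variance partitioning, and indicator-value analysis. A metacommunity
    simulator generates phylogenies, spatial layouts, soil chemistry and
    communities assembled under each of the five processes for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
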