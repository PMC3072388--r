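Package: kinwave
Title: Kinetic Consensus Clustering of Differentiation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Consensus clustering of gene-expression time courses from
    differentiating cell cultures, built around an agreement matrix that pools
    twelve base clustering runs (hierarchical, divisive, fuzzy and medoid
    partitioning under Pearson and Manhattan metrics; k-means, fuzzy c-means,
    a self-organizing map and Gaussian model-based clustering under the
    Euclidean metric). Includes selection of the suggestive cluster number K*
    from agreement-matrix bimodality, agglomeration under a minimum pairwise
    agreement level, permutation-based removal of trivial clusters, kinetic
    wave annotation (early down; transient up, late down; early up; late up),
    EASE-score gene-set enrichment, Yates-corrected contingency tests for
    treatment overlap, differential calling for paired control/treated
    designs, Pfaffl relative-expression and percent-input qChIP calculators,
    and a synthetic-data generator that emulates a seven-time-point,
    four-replicate oligodendrocyte progenitor differentiation microarray
    study with planted kinetic archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    e1071,
    mclust,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
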