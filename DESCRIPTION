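Package: navmix
Title: Noise-Augmented von Mises-Fisher Mixture Clustering of Genetic
    Variant Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters genetic variants by the direction of their
    multi-trait association vectors using a noise-augmented von
    Mises-Fisher mixture model (NAvMix) fitted by an EM algorithm with
    spherical k-means initialisation, BIC selection of the number of
    clusters, and a fixed near-uniform noise component that absorbs
    outlying variants. Includes preprocessing of GWAS summary statistics
    (covariance construction from standard errors and trait correlations,
    standardisation, projection to the unit sphere), a latent-factor
    simulator of genotype-trait data for method evaluation, and
    directional cluster-quality metrics (adjusted Rand index and a
    great-circle silhouette coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
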