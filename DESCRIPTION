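Package: richconn
Title: Rich-Club Analysis of Weighted Structural Brain Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction and analysis of weighted structural brain networks
    from streamline-count, fractional-anisotropy and regional-volume
    ingredients. Implements group-consensus backbones, small-world and
    efficiency metrics normalized against degree-preserving random networks,
    weighted rich-club coefficient curves with null normalization,
    classification of edges into rich-club, feeder and local connections,
    permutation-based group inference with covariate removal, and
    covariate-adjusted Spearman correlation with clinical scores. Includes a
    seeded synthetic-cohort generator that plants rich-club organization,
    a group deficit on hub connections and clinical-score couplings, so the
    whole pipeline can be exercised end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse, knitr
Config/testthat/edition: 3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'atlas.R'
    'simulate.R'
    'io.R'
    'netbuild.R'
    'metrics.R'
    'richclub.R'
    'stats.R'
    'pipeline.R'
RoxygenNote: 7.3.3
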