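Package: riskSOM
Title: Social-Ecological Pattern Discovery for Soil Heavy-Metal Risk
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for regional screening of soil heavy-metal contamination
    and the social-ecological patterns behind it. Computes Hakanson
    contamination factors, per-metal ecological risk and the aggregate
    potential ecological risk index (RI) from point soil samples, carries
    point indices onto administrative units by ordinary kriging and zonal
    averaging, trains a batch self-organizing map (SOM) on unit-level
    covariates, selects map size by quantization and topographic error and
    cluster number by the Davies-Bouldin index of a k-means partition of
    the codebook, and characterizes the resulting clusters with Spearman
    rank correlations, one-way ANOVA and compact-letter post-hoc displays.
    A synthetic-scene generator with planted covariate archetypes supports
    end-to-end validation without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, yaml, jsonlite, pracma
Suggests: testthat (>= 3.0.0), mclust, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, Spatial, Classification
RoxygenNote: 7.3.3
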