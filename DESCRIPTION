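Package: SynDensityNet
Title: Synaptic Density Similarity Connectomes and Imaging Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds subject-level synaptic density similarity connectomes from
    regional PET tracer uptake samples using kernel density estimation and a
    symmetric Kullback-Leibler similarity transform, tests covariate-adjusted
    group differences in nodal connectivity strength with false discovery rate
    control, links regional difference maps to gene expression via partial
    least squares regression with bootstrap z-scores and permutation inference,
    and analyses group-level regional covariance networks with permutation edge
    nulls, signed weighted graph metrics and hub detection. Includes a seeded
    synthetic-data module generating cohorts with planted effects for
    calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, MASS, jsonlite
Suggests: testthat (>= 3.0.0), mixOmics, yaml
biocViews: Network, GraphAndNetwork, Transcriptomics, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SynDensityNet-package.R'
    'covariance-network.R'
    'io.R'
    'methods-accessors.R'
    'network-stats.R'
    'pipeline.R'
    'pls.R'
    'similarity-network.R'
    'synthetic-data.R'
    'utils.R'
    'transcriptomics.R'
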