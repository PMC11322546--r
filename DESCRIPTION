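Package: apexquant
Title: Quantitative Confocal Analysis of Shoot Apical Meristem Shape and
    Reporter Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying shoot apical meristem (SAM) morphology
    and fluorescent-reporter expression from multi-channel confocal
    z-stacks during floral transition. Implements bicubic z-resampling to
    isotropic voxels, semi-automatic paraboloid mask construction from
    parabola fits in orthogonal projections, fluorescence-concentration
    measurement in a depth-limited apical region, half-maximum isocline
    ellipse fitting of expression domains (WUS- and CLV3-type reporters),
    meristem height/width/area morphometrics, and the accompanying
    nonparametric statistical reporting (Mann-Whitney tests per time
    point, one-way ANOVA with Tukey compact letter displays, reference
    normalization and fold changes). A synthetic-stack generator with
    known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'apexquant-package.R'
    'utils.R'
    'stack-io.R'
    'synthetic.R'
    'paraboloid-mask.R'
    'fluor-quant.R'
    'domain-quant.R'
    'shape-metrics.R'
    'stats-report.R'
    'pipeline.R'
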