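Package: habclim
Title: Habitat-Specific Climate-Trait Relationships from Vegetation Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how macroclimate shapes the community-weighted
    means (CWMs) of plant functional traits within hierarchically classified
    habitats. The package reads long-format vegetation-plot, trait, climate and
    habitat tables; applies standard plot exclusion rules and one-plot-per-grid-cell
    spatial stratification; computes cover-weighted trait means with species/genus
    fallback and trait-coverage fractions; summarises 19 bioclimatic variables into
    principal components; fits linear mixed models with habitat random intercepts,
    habitat-specific random climate slopes at three nesting levels and an optional
    low-rank spherical spatial smooth by restricted maximum likelihood; and derives
    habitat-specific marginal slopes, slope-sign tallies and marginal/conditional
    R-squared variance partitions. A synthetic-data generator with known
    mixed-model ground truth supports end-to-end validation and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
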