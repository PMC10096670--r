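Package: prsgxe
Title: Polygenic Score by Diet and Lifestyle Interaction Analysis for Trait
    Impulsivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a gene-environment interaction
    analysis of ADHD polygenic risk, diet quality and lifestyle behaviours on
    trait impulsivity in a large adult population cohort. Provides
    summary-statistic quality control, greedy linkage-disequilibrium clumping,
    multi-threshold polygenic scoring aggregated by principal component
    analysis (PRS-PCA), derived dietary indices (diet-quality score, energy,
    fat and free-sugar excess ratios with Schofield basal-metabolic-rate
    reliability filtering), lifestyle classifications, the staged
    interaction-regression battery with Bonferroni correction and
    socioeconomic-status sensitivity models, and a seeded synthetic-cohort
    generator with linkage-disequilibrium block structure and optional
    gene-environment correlation, so that the whole pipeline is testable
    without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
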