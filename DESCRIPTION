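Package: stereocap
Title: Design-Based Stereology of White-Matter Capillary Networks on
    Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for design-based stereology
    of brain microvasculature. Generates synthetic white-matter regions
    populated with capillary networks of thin cylinders whose total length,
    volume and surface area are known analytically; cuts them with
    systematic Cavalieri slabs and isotropic uniform random (isector)
    section planes; applies the three classical two-dimensional probes
    (unbiased counting frame, point grid, test lines) with exact geometric
    counting rules; and recovers reference volume, capillary length density
    Lv, volume density Vv and surface density Sv with the standard
    unbiased estimators. Includes a two-group cohort generator (wild-type
    vs Tg2576-like) with Morris-water-maze escape-latency series coupled to
    the capillary totals, group statistics (unpaired t test,
    repeated-measures ANOVA) and a structure-behaviour Pearson correlation
    table, so every estimator can be validated against ground truth
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
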