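Package: prsvbm
Title: Polygenic Risk Scores, Permutation Inference and Voxel-Based
    Morphometry
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the full inferential chain from genotype dosages to
    brain and behavior associations: polygenic risk scoring from imputed
    allele dosages, principal-component adjustment for population
    stratification, multiple regression with Freedman-Lane permutation
    p-values and two-stage sharpened (Benjamini-Krieger-Yekutieli) false
    discovery rate control across outcomes, and whole-brain voxelwise
    regression with max-statistic permutation family-wise error correction.
    Includes a synthetic-data generator (genotypes with population
    structure, phenotypes with planted score effects, smoothed volumes with
    planted voxel effects) so every stage is testable end to end without
    external data, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
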