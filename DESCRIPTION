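Package: greensolv
Title: Green-Solvent Screening via Solid-Liquid Equilibrium Solubility and
    Environmental-Index Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rational selection of green solvents for poorly
    soluble solids. Predicts saturation mole-fraction solubility in neat
    and aqueous-binary solvents by iteratively solving the solid-liquid
    equilibrium equation with pluggable activity-coefficient models
    (ideal, multicomponent Margules, NRTL), scores solvents with the
    eight-component PARIS-III-style environmental index (EI) including a
    photochemical-oxidation-excluded variant and an aqueous-mixture
    combination rule, cascades availability / EI / predicted-solubility
    filters into ranked shortlists, and classifies measured binary-solvent
    solubility profiles for co-solvation synergy and water-antisolvent
    behaviour. Seeded generators emulate solvent catalogs and triplicate
    shake-flask measurements so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
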