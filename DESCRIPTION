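Package: dampfos
Title: Daily Accumulation Model for PFOS Residues in Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A one-compartment daily-accumulation toxicokinetic model (DAM)
    for predicting perfluorooctane sulfonate (PFOS) residues in beef cattle
    muscle and serum after oral exposure. Implements day-per-row mass-balance
    accumulation with first-order (half-life) elimination, physiological
    growth and intake submodels (body weight, forage and milk dry-matter
    intake, water and soil ingestion), a weight-of-evidence pooler for
    literature half-life estimates, Monte Carlo uncertainty propagation with
    truncated parameter distributions and rank-correlation sensitivity
    ranking, bioaccumulation-factor derivation, and inverse solving of the
    ration concentration that meets a target tissue residue level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
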