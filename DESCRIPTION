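Package: micellogp
Title: Micelle-Water Partition Coefficients from MEKC Retention and
    Solvation Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts micellar electrokinetic chromatography (MEKC) retention
    measurements into micelle-water partition coefficients (logP) through the
    retention-factor and phase-ratio relations, converts solvation free
    energies into solvent/water logP values, identifies surrogate bulk
    solvents for micellar systems by Pearson correlation and linear
    calibration, applies a substructure exclusion filter for aromatic-ring
    nitrogen and urea-containing compounds, and runs a descriptor-space
    workflow (z-transform, k-means partitioning, PCA variance decomposition,
    and support-vector regression with grid search and cross-validation).
    Ships an experimental 63-compound partition table for sodium cholate
    (SC), hexadecyltrimethylammonium bromide (HTAB), and lithium
    perfluorooctanesulfonate (LPFOS) micelles together with curated
    structures, and a synthetic-data module that emulates the full
    measurement model for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
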