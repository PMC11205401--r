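Package: bilayerlab
Title: Quantitative Analyses of Terpenoid-Membrane Interactions in Model Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative biophysics of small hydrophobic
    solutes in phospholipid bilayers: saturating membrane partition
    isotherms from absorbance data, carboxyfluorescein dye-leakage
    quantification, bilayer trajectory observables (area per lipid,
    lateral diffusion via the Einstein relation, deuterium order
    parameters, phosphate-phosphate thickness, mass density profiles,
    distance-cutoff cluster statistics), WHAM free-energy profiles from
    umbrella-sampling windows, and lamellar SAXS indexing. Every
    analysis is paired with a synthetic-data generator with known
    ground truth so the whole pipeline is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
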