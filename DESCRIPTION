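Package: mecflux
Title: Electron-Flux Accounting and Bioenergetics for Microbial
    Electrolysis Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fed-batch microbial electrolysis cells
    (MECs) fed with fermentable substrates such as propionate: electron-
    equivalent (degree of reduction) stoichiometry, coulombic efficiency
    and hydrogen-production performance metrics, an electron ledger that
    distributes donor electrons over measured sinks (current, methane,
    hydrogen, residual acids) and closes the balance with an undefined
    remainder, an anode-potential Gibbs free-energy model for ranking
    anode respiration against methanogenesis, formula-level microbial
    community metrics (alpha diversity, rarefaction, OTU set sharing,
    domain ratios, abundance tables), and a seeded synthetic-data
    generator that produces batch-cycle measurement sets and OTU tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
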