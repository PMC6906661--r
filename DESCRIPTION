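Package: famescreen
Title: FAME Composition Analysis and Biodiesel Feedstock Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing microalgal (and other) lipid feedstocks for
    biodiesel from their fatty acid methyl ester (FAME) composition profiles.
    Parses lipid shorthand nomenclature (e.g. "C18:3n-3"), computes the
    average degree of unsaturation (ADU) of a profile and five empirical
    fuel properties (kinematic viscosity, specific gravity, cetane number,
    iodine value, higher heating value) from linear correlations on ADU,
    checks the results against ASTM D6751 / EN 14214 biodiesel limits, and
    ranks candidate isolates by culture screening metrics (dry biomass,
    lipid content, volumetric lipid yield, FAME recovery). Ships a worked
    four-isolate freshwater microalgae dataset and a seeded generator of
    synthetic sparse FAME profiles with known ground-truth unsaturation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
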