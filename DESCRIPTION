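Package: ghkselect
Title: Ion Selectivity of Channel-Forming Small Molecules from
    Transepithelial Dilution Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative anion/cation permeability (P_Cl/P_Na) of
    channel-forming small molecules from transepithelial dilution-potential
    experiments in Ussing chambers. Converts bath recipes to ion activities
    with extended Debye-Hueckel activity coefficients, decomposes the
    measured dilution potential into epithelial and drug-pathway components
    with a two-conductance circuit model, and inverts the
    Goldman-Hodgkin-Katz voltage equation in closed form. Also processes
    raw current-clamp recordings into conductance series and protocol-step
    plateaus, quantifies supporting assays (chloride efflux, alamarBlue
    viability, yeast rescue growth, phosphorus standard curves,
    vehicle-normalized secretion), and provides seeded synthetic-data
    generators so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
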