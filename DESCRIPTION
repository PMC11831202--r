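Package: agland
Title: Gridded Partial-Equilibrium Simulation of Agriculture, Land Use,
    Carbon and Biodiversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit partial-equilibrium model of the global
    agri-food economy. Crop production and cropland supply are resolved on
    a grid (CES technology over land and nonland inputs; saturating land
    supply curves calibrated to cultivable-land asymptotes), while demand
    for crops, livestock and processed food clears at the regional level
    with Armington-style imperfect substitution between domestic and world
    crop markets. The package chains multi-period baseline and
    no-improved-varieties counterfactual scenarios, converts the resulting
    cropland differences into one-time land-use-change carbon emissions and
    potential species losses via ecoregion characterization factors, and
    propagates parameter uncertainty with Latin-hypercube sampling. A
    seeded synthetic-world generator emulates the structure of the real
    input data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
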