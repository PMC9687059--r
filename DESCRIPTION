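Package: phytodock
Title: Essential-Oil Composition Profiling, Dose-Response Fitting and
    Docking Post-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for essential-oil phytochemistry and
    structure-based screening. Derives area-percentage composition
    profiles from GC-MS peak tables; computes DPPH percent-inhibition
    and MTT percent-viability statistics and fits logarithmic
    dose-response curves with IC50 estimates; post-processes molecular
    docking output (affinity filtering, Kabsch pose RMSD, contact and
    hydrogen-bond detection); scores enzyme-ligand electronic
    complementarity (CF1 versus SUMRLRE regression) under an
    exponential atomic electron-density model; and evaluates Lipinski
    druglikeness with a local Moriguchi MLOGP implementation. Includes
    seeded synthetic-data generators so every stage runs without
    external downloads, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    igraph,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
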