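Package: hydroshell
Title: pH-Resolved Protein Hydration-Shell Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of protein hydration shells across solution conditions:
    cross-condition clustering of modeled water oxygens into persistent,
    lone and most-persistent sites with nearest-residue assignment;
    hydration-site detection from molecular-dynamics water density grids
    with neighbour smoothing, thresholding and sub-Angstrom peak merging;
    water survival probabilities and residence times around residue
    selections; per-residue bound-water statistics, Shrake-Rupley
    accessible surface area and desolvation trend fits; metal-ion
    displacement geometry; and per-residue pKa estimation from
    constant-pH lambda-coordinate traces via Henderson-Hasselbalch/Hill
    fitting. Ships a seeded synthetic-data generator that plants ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
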