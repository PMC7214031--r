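Package: halidecensus
Title: Census of Halide-Binding Sites in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates X-ray crystal structures from the Protein Data Bank,
    extracts binding sites of monoatomic halide anions (fluoride, chloride,
    bromide, iodide), and computes their coordination geometry: anion-atom
    distances, nearest-atom vector angles, coordination numbers, water
    solvation counts, fractional solvent-accessible surface area, secondary
    structure context and residue composition. Homologous crystallographic
    site copies are merged by Kabsch superposition RMSD. Includes a
    synthetic-PDB fixture generator with known site geometry, census-level
    distribution summaries with ggplot2 graphics, and an end-to-end pipeline
    writing a per-halide tab-separated table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
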