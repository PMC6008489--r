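Package: fragscreen
Title: Kinase Panel Profiling of Fragment Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for fragment-based kinase screening campaigns:
    molecular-formula bookkeeping for HRMS-reported [M+H]+ ions (heavy-atom
    counts, monoisotopic m/z), Cheng-Prusoff IC50-to-Ki conversion under
    stated ATP conditions, ligand-efficiency scoring, compound- and
    kinase-level selectivity scores S(theta) over a single-point panel
    screen, four-parameter logistic dose-response fitting, a seeded
    synthetic panel-screen generator with ground truth for pipeline
    validation, and protein-ligand hinge-contact geometry from PDB
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
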