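Package: pyctools
Title: Phytochelatin and Phytochelatin-Metal Complex Mass Catalogs and
    Accurate-Mass Annotation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministically enumerates elemental formulas and
    monoisotopic masses for phytochelatins (repeating gamma-Glu-Cys
    peptides with variable C-terminal residues), their disulfide
    oxidation states, and their one- and two-metal complexes with 13
    nutritionally and toxicologically relevant metals, including
    sulfido-, disulfido- and selenido-bridged two-metal forms.
    Provides accurate-mass annotation of experimental LC-MS feature
    lists against the generated catalog by adduct m/z matching with a
    ppm tolerance and an optional element-ratio (NOPS) plausibility
    filter, plus a seeded synthetic query generator for validating
    annotation workflows, catalog/query CSV input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
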