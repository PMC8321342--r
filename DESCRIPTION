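Package: mol2narupa
Title: Convert Narupa Builder mol2 Exports to NarupaXR Simulation XML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads TRIPOS mol2 files in both the standard dot-decimal
    dialect and the comma-decimal dialect exported by the Narupa Builder
    virtual-reality molecule editor, validates the molecular graph against
    a valence model, and writes NarupaXR-style simulation XML containing
    coordinates, bonds, temperature and per-atom MM3/Lennard-Jones
    force-field mapping entries. Also provides the builder-side chemistry
    operations as library functions: valence-based bond feasibility,
    bond-order editing, hydrogen balancing, and harmonic bond-length
    minimization, plus an MM3-style glossary loader for automatic atom
    typing and a fixture generator for small test molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
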