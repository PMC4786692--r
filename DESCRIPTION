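Package: dualreach
Title: Geometry, Stoichiometry and Binding Models for Dual-Domain-Antibody
    Antigen Engagement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how multivalent antibody formats engage
    homodimeric antigens such as VEGF. Reads macromolecular structures,
    superposes complexes on a shared antigen (Kabsch), measures
    inter-terminal C-alpha distances and crystal solvent content, tests
    whether peptide linkers can span the measured separations (end-on
    versus side-on engagement), enumerates feasible binder:antigen complex
    species with predicted masses, inverts multi-detector SEC-MALLS traces
    to molar-mass profiles via the zero-angle Debye-Zimm relation, and fits
    1:1 Langmuir SPR kinetics, four-parameter logistic dose-response
    curves, and equilibrium competition models of receptor-binding
    inhibition. Includes deterministic synthetic-data generators for every
    input so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    igraph,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
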