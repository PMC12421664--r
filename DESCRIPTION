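Package: ledkit
Title: Local Energy Decomposition Workflows for Molecular Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automating local energy decomposition (LED) analyses of
    molecular interactions: fragment detection from XYZ geometries via covalent
    radii, enumeration and rendering of all quantum-chemistry inputs needed for
    N-body and two-body LED with and without counterpoise (BSSE) correction,
    parsing of LED output files into component-resolved interaction-energy
    matrices (standard and fragment-pairwise layouts), cooperativity analysis,
    two-point complete-basis-set (CBS) and complete-PNO-space (CPS)
    extrapolation, and CSV/heat-map reporting. A ground-truth mock-output
    generator makes the whole pipeline testable without a quantum-chemistry
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
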