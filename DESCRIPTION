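Package: autocg
Title: Automated Coarse-Grained Mapping and Martini Topology Generation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds Martini-2-compatible coarse-grained models of organic
    molecules directly from SMILES strings. Heavy atoms are partitioned into
    beads by spectral graph grouping with pattern-based treatment of fused
    five- and six-membered ring systems, bead types are assigned from fragment
    octanol-water transfer free energies and hydrogen-bonding character,
    bonded terms are averaged over torsional conformer ensembles, and rigid
    ring systems are rendered as minimal constraint networks with virtual
    sites and hinge dihedrals. Writes GROMACS-dialect topology (.itp),
    coordinate (.gro) and mapping files. Also provides an adaptive-cutoff
    estimator of membrane-water partition coefficients from free-energy
    profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
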