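Package: torsionsmith
Title: Ligand-Specific Torsion Reparameterization for AMBER Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated refitting of small-molecule dihedral parameters for
    AMBER/GAFF2-style force fields. Reads AMBER topologies, generates and
    clusters conformer ensembles, identifies chemically significant rotatable
    torsions, optionally fragments the molecule around torsion regions with
    methyl capping, drives restrained 360-degree dihedral scans against a
    pluggable reference backend, and refits Fourier torsion terms (and
    optionally 1-4 scaling factors) by bounded quasi-Newton least squares,
    emitting frcmod, parmed-script, mol2 and atom-map outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
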