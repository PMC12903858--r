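Package: glycoSAXS
Title: Conformational Populations of Flexible Glycans from SAXS and
    Molecular Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semiautomated quantification of the degree of folding of
    flexible (glyco)foldamers in solution. Classifies molecular-dynamics
    trajectory intervals into radius-of-gyration-defined conformational
    states (folded and unfolded ensembles), predicts small-angle X-ray
    scattering (SAXS) profiles per state ensemble with Cromer-Mann atomic
    form factors via exact Debye summation or Monte-Carlo orientational
    averaging, and fits constrained linear combinations of the predicted
    curves to an experimental SAXS curve to estimate conformational
    populations. Includes Guinier and Kratky analysis, glycosidic
    dihedral and CH...O hydrogen-bond diagnostics, readers for PDB, GRO
    and ASCII scattering data, and a seeded two-state synthetic
    trajectory generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
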