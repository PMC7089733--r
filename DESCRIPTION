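Package: presas
Title: Integrative PRE and Small-Angle Scattering Ensemble Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies paramagnetic relaxation enhancement (PRE) intensity
    ratios into distance restraints, back-calculates PRE and small-angle
    scattering (SAXS/SANS with contrast matching) observables from bead-model
    conformers, partitions distance restraints between conformational states,
    selects mixed conformational ensembles with a pseudo-genetic consensus
    scoring algorithm, and converts state populations into free-energy
    differences. Includes a synthetic two-site complex generator so the whole
    pipeline is testable without experimental downloads, plus readers and
    writers for PDB-subset coordinates, three-column scattering curves and
    tab-separated PRE tables, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'sas.R'
    'pre.R'
    'restraints.R'
    'partition.R'
    'select.R'
    'thermo.R'
    'synthetic.R'
    'io.R'
    'cli.R'
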