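Package: CGPepDock
Title: Contact-Guided Coarse-Grained Protein-Peptide Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flexible protein-peptide docking with a coarse-grained chain
    representation (CA, CB, side-chain center and peptide-bond center
    pseudo-atoms), replica-exchange Monte Carlo sampling of a fully flexible
    peptide around a near-rigid fluctuating receptor, and incorporation of
    fragmentary residue-residue contact information as soft distance
    restraints between side-chain centers. Includes interaction-energy and
    contact-criterion filtering of docking trajectories, k-medoids
    clustering of filtered models, model-quality evaluation against a
    reference complex (peptide-RMSD, interface-RMSD, accuracy categories),
    and a deterministic generator of toy receptor-peptide systems with
    planted binding pockets for fully offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cgComplex-methods.R'
    'coarseGrain.R'
    'buildPeptide.R'
    'io.R'
    'restraints.R'
    'forcefield.R'
    'sampler.R'
    'trajectory-methods.R'
    'postprocess.R'
    'evaluate.R'
    'fixtures.R'
    'CGPepDock-package.R'
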