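Package: flexbuild
Title: Automated Multi-Conformer Side-Chain Model Building from Electron-Density Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alternative side-chain conformations in crystallographic
    electron-density maps by Ringer-style sampling of map density around each
    side-chain dihedral (chi) angle, finds peaks in the resulting circular
    density traces, assembles peak angles into candidate rotamers validated
    against an ideal rotamer library, and explicitly builds the surviving
    rotamers into the model as altloc-labelled, occupancy-weighted alternate
    conformers ready for crystallographic refinement.  Includes a synthetic
    Gaussian-atom map generator with ground-truth multi-conformer fixtures so
    the full pipeline is testable without deposited data, plus real-space
    correlation and normalized B-factor validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
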