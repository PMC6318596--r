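Package: tactigel
Title: Tacticity-Dependent Association Analysis of Two-Chain PNIPAM Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of stereochemistry-dependent inter-chain association of
    poly(N-isopropylacrylamide) (PNIPAM) in molecular dynamics style
    trajectories. Provides meso/racemo dyad-sequence bookkeeping and
    Bernoullian sequence generation, multi-frame GRO/PDB trajectory input and
    output with periodic-boundary minimum-image distances, inter-chain contact
    detection with atom-class cutoffs calibrated from radial distribution
    function first minima, junction-topology statistics (number of junctions,
    mean junction length, contacting residues), inter-residue minimum-distance
    maps, radius of gyration, end-to-end distance, Shrake-Rupley solvent
    accessible surface area, and literature-coefficient estimates of hydration
    free-energy differences and microgel swelling ratios. A seeded synthetic
    two-chain trajectory generator with plantable contact patterns supports
    testing and demonstration without atomistic simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), bio3d, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
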