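Package: memtraj
Title: Analysis of Coarse-Grained Protein-Membrane Trajectories and
    Matched Solution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bead-resolution (coarse-grained) simulations
    of peripheral and single-pass membrane proteins near lipid bilayers:
    protein-lipid contact-fraction profiles split by lipid head-group and
    acyl-chain beads, residue-residue contact maps, membrane-bound-state
    detection and statistics, two-dimensional lipid density and
    enrichment/depletion maps, backbone RMSF, and geographic
    (latitude/longitude) classification of membrane-bound orientation states
    of a rigid domain. Companion routines analyse the matched solution
    experiments used to validate such simulations: NMR chemical shift
    perturbations, titration intensity ratios, secondary chemical shifts,
    transverse relaxation (R2) decay fitting, circular dichroism processing,
    and confocal line-scan membrane-localization ratios. A synthetic-data
    module generates bilayer and protein trajectories with planted ground
    truth (compositions, enrichment discs, orientation-state schedules,
    contact fractions, correlated titration profiles) for end-to-end
    validation. Reads and writes GRO structures, multi-frame GRO and DCD
    trajectories, and PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
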