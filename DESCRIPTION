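Package: portaldyn
Title: Trajectory Analytics for Helical Portal Dynamics in Lipid-Presenting Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    antigen-presenting proteins whose binding groove opens through a portal
    between two alpha-helices (the CD1d alpha1/alpha2 architecture).
    Computes fractional occupancy-volume grids with OpenDX export, per-frame
    solvent-accessible surface area (Shrake-Rupley) with Savitzky-Golay
    smoothing, side-chain chi1 dihedral traces with circular statistics and
    g+/trans/g- rotamer classification, consensus pKa merging across
    predictor outputs with pH-dependent protonation and net-charge
    assignment (PQR export), backbone hydrogen-bond based alpha-helix
    segmentation with hinge detection, and Kabsch superposition with
    pairwise-RMSD matrices and classical multidimensional scaling.  A
    synthetic-trajectory module generates portal, rotamer and pKa fixtures
    with known ground truth so every stage is testable without simulation
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
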