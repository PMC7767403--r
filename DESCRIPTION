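Package: bindshift
Title: Effect of a Regulatory Base-Pair Substitution on Transcription
    Factor-DNA Binding from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis of how a single regulatory base-pair
    substitution (A:T to G:C) changes a transcription factor's binding to
    DNA.  Provides Kabsch superposition and RMSD-based rigidity comparison,
    strictly geometric hydrogen-bond and water-bridge detection with
    occupancy and lifetime statistics, and linear interaction energy (LIE)
    binding free energies combined through a four-system thermodynamic
    cycle into a relative binding free energy (ddG_bind) with replicate
    pooling and block-averaged uncertainties.  A synthetic-data generator
    builds idealized B-DNA duplexes, toy protein-DNA complexes with
    bridging waters, noise trajectories with controllable rigidity, and
    AR(1) interaction-energy series, so the whole pipeline runs without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
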