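Package: enzdyn
Title: Molecular Dynamics Trajectory Analysis for Enzyme Flexibility and
    Interaction Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular dynamics trajectories of
    proteins, centred on the comparative profiling of enzyme flexibility
    and interaction networks. Provides least-squares (Kabsch)
    superposition, RMSD time series, per-residue mass-weighted RMSF and
    B-factor profiles with sequence-alignment based matching between
    homologues, geometric hydrogen-bond detection with static and dynamic
    trajectory statistics, salt-bridge and ligand-contact occupancy
    tables, Shrake-Rupley solvent-accessible surface area, dynamic
    cross-correlation matrices, essential-dynamics principal component
    analysis, Boltzmann-inversion free-energy landscapes, and
    block-average standard errors.  A synthetic-trajectory module
    generates ensembles with analytically known fluctuations,
    correlations, basin occupancies and interaction schedules so that
    every stage is verifiable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
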