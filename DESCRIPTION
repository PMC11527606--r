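Package: poregate
Title: Gating and Permeation Analysis of Ion-Channel MD Trajectories
Version: 0.1.0
Authors@R:
    person("poregate", "developers", email = "poregate@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    tetrameric ion channels. Reads PDB topologies and DCD/XTC/multi-model
    PDB trajectories, resolves residue and atom selections with a small
    query grammar, and computes the quantities used to characterise
    channel gating: per-frame gate aperture distances and open fractions,
    directional potassium permeation event counts via a hysteretic state
    machine, ion occupancy and dwell-time statistics per pore region and
    residue, salt-bridge/hydrogen-bond/hydrophobic contact-fraction
    networks and their apo-vs-holo differences, combined principal
    component analysis of concatenated ensembles, residue-pair
    displacement correlation matrices, and circular-statistics summaries
    of backbone phi/psi torsions. A synthetic toy-channel trajectory
    generator with planted, manifest-recorded ground truth (gate
    schedules, scripted ions, contact fractions, correlations, torsions)
    makes every analysis testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
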