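Package: taupatch
Title: Trajectory Analysis of Fibril-Interface Patch Exposure and
    Ligand Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    aggregation-prone proteins, built around the solvent exposure of a
    fibril-interface residue patch (by default the tau K18 GGG patch,
    residues 333-335) and its coupling to residue-ligand contact
    reorganization.  Provides readers and writers for multi-model PDB
    and XYZ trajectories, Kabsch superposition RMSD and radius-of-gyration
    time series with kernel-density summaries, Shrake-Rupley
    solvent-accessible surface area with threshold classification and
    per-segment statistics, residue-ligand contact frequencies with
    gained/lost differential analysis between trajectory halves, and
    seeded coarse-grained trajectory generators with recorded ground
    truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
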