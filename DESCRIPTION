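Package: fluctnet
Title: Efficacy-Linked Fluctuating Network Analysis of Receptor Coordinate Ensembles
Version: 0.1.0
Authors@R:
    person("fluctnet", "developers", email = "fluctnet@example.org", role = c("aut", "cre"))
Description: Analysis of paired active/inactive coordinate ensembles of a
    receptor bound to a ligand panel. Computes per-atom root mean square
    fluctuations (RMSF) and per-pair cross-correlation statistics (the root
    sum of the squared components of the 3x3 Pearson correlation submatrix,
    "PCC"), forms active-minus-inactive differences per ligand, correlates
    them with per-ligand G-protein and beta-arrestin efficacies across the
    panel to extract a network of fluctuating atoms and atom-atom couplings,
    and scores region means that track ligand efficacy and bias. Includes a
    multi-model PDB reader/writer, Kabsch ensemble superposition, a
    synthetic-ensemble generator with planted efficacy-scaled collective
    modes for end-to-end testing, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
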