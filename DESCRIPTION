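Package: poretrans
Title: Langevin Dynamics and Analysis of Polyelectrolyte Nanopore Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Langevin dynamics of a charged bead-spring polymer
    driven through a nanopore in a membrane wall, together with the analysis
    toolkit used to characterize the process: simulation-to-real unit mapping
    (including the Odijk-Skolnick-Fixman persistence length), gyration-tensor
    shape descriptors (shape factor, asphericity, prolateness, principal-axis
    angles), bond-tension propagation diagnostics, waiting-time statistics of
    the translocation coordinate, and drift-diffusion characterization with
    log-normal first-passage fits. Trajectories are read and written in
    extended-XYZ and LAMMPS-dump dialects, and deterministic synthetic
    fixtures (rigid rods, random coils, log-normal passage times, ramped
    tension chains) make every analysis testable without running dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
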