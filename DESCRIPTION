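Package: circlet
Title: Circular Cell-Cycle Trajectory Reconstruction from Single-Cell Hi-C
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Orders single cells along the cell cycle from sparse single-cell
    Hi-C contact maps without specifying a starting cell. Multiscale chromatin
    features (contact-distance distributions, pairwise contact coverage,
    insulation scores, composite contact metrics) are embedded with diffusion
    maps; cells are ordered by shortest-path distances on a k-nearest-neighbor
    graph, the circle is split into two semicircles via waypoint disagreement,
    and each semicircle ordering is refined by Gaussian-weighted waypoint
    perspectives until convergence, yielding a circular pseudotime in [0,1].
    Includes trajectory scoring against FACS phase labels (label change score
    and successive-phase AUC), division of the trajectory into cell-cycle
    substages, insulation-based TAD boundary dynamics, aggregate loop
    analysis, and a seeded synthetic single-cell Hi-C generator with known
    circular ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
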