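Package: trajcomp
Title: Comparative Analysis of Molecular Dynamics Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the structural dynamics of a wild-type
    protein complex against point variants from molecular dynamics
    trajectory ensembles. Reads topologies (PDB, GRO) and trajectories
    (multi-model PDB, DCD, multi-frame GRO), pools equilibrated replicas and
    superposes frames; quantifies protein-protein interfaces (buried
    surface area via Shrake-Rupley sampling, heavy-atom contact counts,
    hydrogen-bond occupancy, shortest van der Waals contacts); computes
    distance-fluctuation matrices and the per-residue normalized distance
    fluctuation (NDF) score with variant-minus-wild-type differences;
    computes dynamic cross-correlation matrices, their difference matrices
    with cosine and Spearman similarity, and essential-dynamics PCA with
    per-region involvement fractions. A synthetic-ensemble generator with
    programmable correlation blocks, interface strength, hydrogen-bond
    occupancy and regional disorder provides ground truth for validation,
    and a pipeline driver orchestrates full wild-type-versus-variant
    comparisons from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
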