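Package: pairforce
Title: Force Distribution Analysis for Molecular Dynamics Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of molecular dynamics coordinate trajectories
    into pair-wise atomic forces (force distribution analysis). Computes
    signed scalar pair forces for bonded (bond, angle, proper dihedral) and
    non-bonded (cutoff Coulomb, Lennard-Jones) interactions, stores them as
    sparse force trajectories in a compact binary format, and provides the
    statistical layer used to detect mechanical strain propagation: time
    averages with variances, cross-run standard errors, force differences
    between perturbed and reference states, noise normalization, per-atom
    projection written to PDB b-factors, residue-level aggregation (scalar
    and vector), force-network extraction and principal component analysis
    of force time series. A synthetic-systems module generates toy
    topologies and trajectories with known analytic force structure for
    validation, and a command-line interface exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
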