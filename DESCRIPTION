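Package: dimerpull
Title: Peptide Dimer Ensemble Analysis and Monte Carlo Pulling Force
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing conformational ensembles of small
    amyloidogenic peptide dimers and for validating candidate dimer
    conformations against single-molecule force spectroscopy data.
    Provides dihedral-criterion secondary-structure assignment and
    windowed time series, a reduced hydrogen-bond (DSSP-like) assigner,
    GROMOS RMSD clustering, dihedral principal component analysis with
    free-energy landscapes and minima detection, C-alpha contact
    probability and difference maps, geometric shape descriptors
    (radius of gyration, convex-hull volume, Shrake-Rupley solvent
    accessible surface area), a Metropolis Monte Carlo pulling engine on
    a structure-based (Go-type) energy backend producing force-extension
    traces and rupture statistics, and statistical machinery (Gaussian
    mixture peak fitting, contour-length normalization, two-sample
    Kolmogorov-Smirnov comparison) to rank candidate conformations
    against a reference rupture dataset. A synthetic-data module
    generates peptide ensembles, docked dimers, and Gaussian-mixture
    rupture datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
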