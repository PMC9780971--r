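Package: znfdyn
Title: Coevolution, Essential Dynamics, Pulling Work and Pocket Volumetrics
    for RNA-Binding Zinc Fingers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for dissecting how tandem CCCH zinc-finger
    RNA-binding domains (the MBNL family being the motivating case)
    differentiate their binding behaviour.  Implements sequence conservation
    and coevolution statistics over multiple sequence alignments
    (Kullback-Leibler conservation, mutual information with average-product
    correction and permutation Z-scores, cumulative and structure-aware
    proximity MI), essential-dynamics analysis of coordinate ensembles
    (iterative Kabsch superposition, covariance-mode decomposition,
    fluctuation profiles, RMSIP subspace overlaps, RMSD), analysis of
    constant-velocity steered-pulling work ensembles (cumulative work with
    confidence bands, Jarzynski and second-cumulant potential-of-mean-force
    estimates, rupture-point detection, segment-wise fluctuations), and
    POVME-style grid-based pocket volumetrics.  A synthetic-data module
    generates every input class with known ground truth (planted-signal
    alignments, low-rank-plus-noise coordinate ensembles, overdamped Langevin
    pulling trajectories, toy pocket scenes) so each stage is verifiable
    without cluster-scale molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
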