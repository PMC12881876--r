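Package: suturemorph
Title: Ontogenetic Shape and Complexity Analysis of Cranial Sutures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparative ontogenetic analysis of cranial
    suture morphology from 3D landmark and semilandmark data. Provides readers
    for TPS and CSV landmark files, thin-plate-spline estimation of missing
    landmarks, midline mirroring, arc-length curve resampling, bending-energy
    semilandmark sliding, generalized Procrustes superimposition with passive
    transformation of suture semilandmarks, 2D projection of suture curves
    (including specimen-specific rotation of the coronal suture), box-count
    fractal dimension and short-time-Fourier power-spectrum complexity scores,
    permutation (RRPP) Procrustes ANOVA and phylogenetic MANOVA, Procrustes
    variance disparity, ontogenetic allometric trajectory comparison,
    Brownian-motion maximum-likelihood ancestral state estimation, and
    simulation-based phylogenetic ANOVA. Includes a synthetic suture-ontogeny
    generator so the whole pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
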