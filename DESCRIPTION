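Package: kinhelix
Title: Helical Microtubule Cryo-EM Reconstruction and Kinesin Motility Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for the image-processing and quantitative
    statistics used in structural studies of motor-decorated microtubules.
    Implements the pseudo-helical microtubule lattice geometry (13-15
    protofilaments, 3-start, seam), synthetic generators for decorated-MT
    volumes, projected segment stacks with known ground truth, and
    single-molecule assay datasets; an IHRSR-style refinement loop
    (projection matching, asymmetric back-projection, helical-parameter
    estimation, N-fold symmetrized averaging, protofilament-number sorting,
    per-filament alignment smoothing); protofilament-level wedge-mask signal
    subtraction, particle extraction, local refinement and focused
    classification; Fourier shell correlation with the 0.143 criterion,
    B-factor sharpening and windowed local resolution; and fitters for
    Michaelis-Menten ATPase kinetics, Gaussian-mixture velocity and
    intensity distributions, right-censored exponential run lengths,
    force-per-overlap scaling and spindle-to-cytoplasm intensity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    survival,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
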