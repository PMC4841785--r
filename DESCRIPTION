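Package: gridpca
Title: Grid-Cell Pattern Formation from Place-Cell Inputs by Non-Negative PCA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the emergence of entorhinal grid cells from hippocampal
    place-cell input in a single-layer Hebbian network. Simulates an agent's
    random walk over a square arena tiled with place-cell tuning curves
    (Gaussian, difference-of-Gaussians, or signed disks), trains Oja and
    Sanger (generalized Hebbian) networks with an optional non-negativity
    constraint on the feedforward weights, and solves the equivalent
    steady-state non-negative PCA problem directly with a projected
    accelerated gradient (FISTA-style) method on the spatial convolution
    objective. Includes the associated ordinary-differential-equation
    stability analysis, spatial autocorrelogram gridness scoring (hexagonal
    and square), grid spacing, orientation, alignment and module detection,
    and the Fourier-lattice theory of the steady states (tuning-curve
    transform peak, PCA solution degeneracy, one-dimensional coefficient
    scans and lattice-type objective bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
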