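Package: gpes
Title: Diffuse-Boundary Continuum Solvation via the Generalized Poisson
    Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implicit-solvent electrostatics with a cavity-free, diffuse
    dielectric boundary. The solvent is a continuum with a
    position-dependent permittivity built from interlocking smoothed
    atom-centered spheres; the generalized Poisson equation
    div(eps(r) grad V) = -4 pi rho is solved on a uniform Cartesian grid
    by a self-consistent reaction field (SCRF) iteration with
    Krylov-accelerated inexact Newton (KAIN) convergence acceleration.
    Includes free-space Poisson solution by zero-padded kernel
    convolution, analytic Born and Onsager sharp-cavity references,
    brute-force and sparse finite-difference oracles, XYZ input and
    Gaussian cube volumetric output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
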