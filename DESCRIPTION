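Package: pipfit
Title: Permutationally Invariant Polynomial Potential Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction of permutationally invariant polynomial (PIP)
    bases in Morse-transformed interatomic distances, weighted linear
    least-squares fitting of molecular potential energy surfaces to
    electronic energies, fast analytic gradients by reverse-mode
    differentiation of the polynomial evaluation graph, and downstream
    analyses of the fitted surface: diffusion Monte Carlo zero-point
    energies, harmonic normal-mode analysis at stationary points, and
    relaxed minimum-energy dissociation paths by simulated-annealing
    trajectories. Includes analytic toy potentials and synthetic dataset
    generators so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
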