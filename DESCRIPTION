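Package: flocknet
Title: Consensus Robustness of Nearest-Neighbour Flock Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how robustly a flock of animals can maintain
    consensus (e.g. on a direction of travel) when every individual senses
    only its m nearest neighbours and all information is corrupted by noise.
    Builds directed m-nearest-neighbour sensing graphs from 3-D positions,
    measures steady-state disagreement as the H2 norm of the noisy consensus
    dynamics via the Lyapunov equation on the reduced graph Laplacian, and
    locates the number of neighbours m* that maximises robustness per
    neighbour. Includes inertia-ellipsoid shape descriptors (thickness,
    width), generators for synthetic flocks (uniform, Halton quasi-random,
    perturbed grid) of controlled shape, sweep and ensemble analyses, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
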