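Package: polarphase
Title: Phase Reduction of Reaction-Diffusion Models of Tissue Polarity
Version: 0.1.0
Authors@R:
    person("polarphase", "maintainers", email = "polarphase@example.org",
           role = c("aut", "cre"))
Description: Tools for reducing coupled reaction-diffusion models of planar
    cell polarity to geometry-aware phase models. Each cell carries a
    reaction-diffusion system on its periodic boundary and interacts with its
    neighbours through shared contact surfaces; under weak coupling the state
    of a cell collapses to a single polarity angle. The package computes the
    steady polarity pattern, its adjoint zero eigenfunction (phase sensitivity
    function) and the pairwise phase coupling function, both from a Fourier
    expansion and by direct quadrature; builds hexagonal tissue graphs
    (chains, winding alignments, periodic sheets, with cell elongation and
    per-edge coupling heterogeneity); and simulates both the full
    reaction-diffusion tissue and the reduced phase model, deterministically
    or with noise and external orienting signals, including potential and
    Boltzmann stationary-density analysis for gradient-type couplings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
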