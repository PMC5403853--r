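Package: multirate
Title: Multirate Co-Simulation of Coupled ODE Components with Decoupled BDF2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for co-simulation of mutually coupled ordinary differential
    equation components evolving on widely separated timescales, as found in
    electrical-chemical multiscale models in neuroscience. Each component is
    advanced by an adaptive second-order backward differentiation formula
    (BDF2) on its own non-uniform time grid; components are organized in a
    Gauss-Seidel fashion (fast-first or slow-first) with synchronous or
    asynchronous communication of exchanged variables, which are approximated
    between communication points by second-order polynomials. A coupled error
    control rule constrains each slower component's step by the maximum
    discretization error of its faster neighbours. Includes an
    electrical-chemical test case (multi-compartment Hodgkin-Huxley neuron
    coupled to a reduced bistable MAPK signalling cascade through calcium),
    synthetic two-timescale benchmark problems with reference solutions, and
    an evaluation harness measuring accuracy against monolithic stiff
    reference solves versus the number of right-hand-side evaluations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
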