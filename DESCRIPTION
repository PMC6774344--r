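Package: pnpgel
Title: Poisson-Nernst-Planck Electrodiffusion in Fixed-Charge Hydrogel Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-element simulator for coupled electro-diffusive ion
    transport (Poisson-Nernst-Planck) in a polyelectrolyte hydrogel scaffold
    immersed in a NaCl bath, the setting used when electrically stimulating
    cartilage-tissue-engineering constructs. Provides the closed-form Donnan
    equilibrium for a monovalent binary electrolyte against a fixed anionic
    charge, graded 1D/2D meshes (interval, square gel, circular scaffold) with
    local refinement bands at the gel-solution interface, Lagrange elements of
    order 1-3, damped Newton and Gummel solvers for the stationary system,
    backward-Euler transient stepping, chemical and constant-voltage electrical
    stimulation protocols, line-profile extraction, steady-state detection,
    electroneutrality diagnostics, Gmsh MSH and legacy-VTK export, and a JSON
    configuration layer with presets for the standard stimulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
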