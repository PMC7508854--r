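Package: tjumpmelt
Title: Equilibrium Thermodynamics and Temperature-Jump Kinetics of
    DNA-Ligand Melting Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action models for DNA duplex melting with and without a
    minor-groove ligand bound: two-state duplex dissociation (D <-> 2S),
    two-state concerted complex dissociation (DH <-> H + 2S) and a stepwise
    three-state scheme (2S <-> D, D + H <-> DH), with van't Hoff
    thermodynamics, SVD extraction of melting curves from temperature-series
    infrared spectra, global two-state fitting across concentrations,
    Eyring analysis of temperature-jump relaxation rates, a maximum-entropy
    inverse Laplace transform for rate distributions of log-time kinetic
    traces, transient band integration, and a seeded synthetic-data
    generator that emulates the full experimental pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
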