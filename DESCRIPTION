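Package: sflt1sim
Title: Mechanistic Models of sFLT1 Secretion Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compartmental kinetic models of the production, maturation,
    secretion and degradation of soluble FLT1 (sFLT1/sVEGFR1) by endothelial
    cells. Provides a family of eight candidate ordinary and delay
    differential equation models linking intracellular and extracellular
    sFLT1 pools, simulation protocols for constitutive-secretion and
    pulse-chase experiments, multistart bounded nonlinear least-squares
    fitting to time-course data, small-sample-corrected Akaike model
    selection, flux decomposition, local and global univariate sensitivity
    analysis, simulation of chemical and genetic inhibition with inversion
    of observed fold changes into effective inhibition fractions, and a
    synthetic-data generator emulating the designs of published sFLT1
    secretion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
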