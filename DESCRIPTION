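Package: phenodrift
Title: Phenotype-Structured Population Dynamics of Heterogeneous
    Formaldehyde Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the dynamics of continuously distributed formaldehyde
    tolerance in clonal Methylobacterium extorquens populations as a
    phenotype-structured advection-diffusion-selection partial differential
    equation in one-dimensional tolerance space.  Provides utilities to
    prepare colony-count (CFU) tolerance-distribution time series measured
    by selective plating (cumulative/non-cumulative transforms, a
    detection-limit extension rule, replicate averaging, monotone spline
    interpolation to the model grid), a method-of-lines solver for the
    growth/death/diffusion/advection dynamics, maximum-likelihood parameter
    estimation on the inverse-hyperbolic-sine scale with Hessian standard
    errors and stepwise likelihood-ratio model selection, exponential
    growth- and death-rate regressions from CFU time series, and a
    synthetic-data generator emulating the serial-dilution plating
    observation process with its detection limit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
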