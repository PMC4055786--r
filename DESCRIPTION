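Package: pkpdtrial
Title: Pharmacokinetic-Pharmacodynamic and Clinical Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for compartmental
    pharmacokinetic-pharmacodynamic (PK/PD) simulation and clinical trial
    simulation. Provides fixed-step (Euler, midpoint, classical Runge-Kutta)
    and adaptive stiff ODE integration with exact, reproducible handling of
    bolus and infusion dosing events; a library of structural PK and PD
    models including transit-compartment absorption and full-binding
    target-mediated drug disposition; correlated lognormal interindividual
    variability via Cholesky factorization; two fully parameterized trial
    simulators (a blood-pressure dose-success design and a
    flare/randomized-withdrawal design with binomial visit events);
    parameter sweeps, summary statistics, least-squares model fitting, and
    delimited-text import/export with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
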