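Package: ssdopt
Title: Surrogate-Assisted Sample Size Determination for Complex Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves simulation-based sample size determination problems with
    several design parameters, several objectives to minimise, and operating
    characteristic constraints (power, type I error) that must be estimated by
    Monte Carlo. Gaussian-process surrogate models of the Monte Carlo estimates
    drive a constrained multi-objective efficient global optimisation (EGO)
    loop built on expected hypervolume improvement, returning a Pareto
    approximation set of candidate trial designs. Includes a fixed space-filling
    comparator, exact 2-D/3-D dominated-hypervolume computation, a Sobol
    quasi-random design generator, a particle swarm inner optimiser, and two
    built-in example problems: an analytically tractable cluster randomised
    trial and a two-endpoint trial with partially nested and crossed clustering
    analysed by mixed-model likelihood ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
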