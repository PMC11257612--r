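Package: chemosense
Title: Information Rates and Physical Limits of Bacterial Chemosensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the chemosensory performance of run-and-tumble
    bacteria against the physical limit set by stochastic ligand-molecule
    arrivals at their receptors. Provides linear Gaussian forward models of
    the behaviorally-relevant signal (the temporal derivative of
    log-concentration experienced by a swimming cell), of diffusive molecule
    arrivals, and of receptor-kinase activity with adaptation and internal
    noise; steady-state causal filtering theory (algebraic Riccati and
    Wiener-Hopf spectral-factorization solvers) yielding behaviorally-relevant
    information rates, signal-to-noise ratios and sensing efficiencies;
    synthetic-data generators emulating single-cell tracking, step-response
    and constant-background fluorescence experiments; the corresponding
    parameter-estimation pipeline (tumble detection, velocity autocorrelation
    fits, response-kernel and Ornstein-Uhlenbeck noise fits by maximum a
    posteriori estimation with ensemble MCMC uncertainties, and population
    aggregation); and agent-based run-and-tumble chemotaxis simulations
    linking information rates to gradient-climbing speed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
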