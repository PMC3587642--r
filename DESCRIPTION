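Package: fireflyde
Title: Hybrid Firefly-Differential Evolution Estimation of Biological ODE Model Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parameter estimation for nonlinear kinetic models of biochemical
    networks using a hybrid metaheuristic that couples Firefly Algorithm
    neighbourhood search with Differential Evolution mutation, crossover and
    greedy selection on the fitter half of the swarm, while the weaker half is
    re-seeded around the incumbent best solution. Ships two study systems (a
    p53-Mdm2 negative feedback loop and an arginine catabolism pathway, with
    perturbed variants), an in-silico noisy time-series generator, a
    chi-square practical-identifiability test based on residual variance
    intervals, and AIC-based model selection, plus a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
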