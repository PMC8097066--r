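Package: cellhydro
Title: Markov-Type Stochastic Modelling of Acid Cellulose Hydrolysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic depolymerization kinetics for dilute-acid hydrolysis
    of cellulose. Chains are discretized into molecular-mass classes on a
    cellobiose ladder; bond scission is modelled as an absorbing Markov
    chain whose transition probabilities follow Gauss or Weibull scission
    distributions, with mass-weighted transitions, acid-concentration and
    temperature modulation of transition frequencies, discrete-time and
    continuous-time (RK4) evolution of the class mass-fraction vector, the
    deterministic first-order cellulose to glucose to hydroxymethylfurfural
    reference model, and RMSE/CV agreement metrics between the two model
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
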