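Package: mmselect
Title: Predictive Bayesian Order Selection for Multistep Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form predictive Bayesian model selection for multistep
    (higher-order) and variable-length Markov chains over finite state
    alphabets, using Dirichlet conjugate priors.  Computes AIC, BIC and the
    marginal-likelihood, predictive-density, WAIC, DIC and cross-validation
    (leave-one-out and leave-half-out) criteria exactly, without sampling or
    refitting, from transition counts.  Includes a trajectory simulator for
    random multistep networks with absorbing states and for synthetic
    free-throw seasons, and replication of simulation studies of
    selection-criterion performance and power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
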