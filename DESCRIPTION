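Package: adaptepi
Title: Coupled Epidemic-Behavior Simulation with Heterogeneous Adaptive Contact Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-risk-group SEIAR epidemic in which susceptible
    (and, through misperception of their own health state, exposed and
    asymptomatic) individuals choose daily contact rates by solving
    finite-horizon Markov decision problems via backward induction. The
    epidemic state and the privately optimal contact choices feed back into
    each other day by day. Provides the constant-contacts baseline model,
    next-generation-matrix reproduction numbers, final-size utilities,
    parameter-sweep machinery for attack-rate trade-off experiments
    (risk-group composition, risk reduction, disease reporting levels,
    planning horizons), and scenario configuration via YAML.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
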