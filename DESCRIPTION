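Package: combilearn
Title: Emergence of Combinatorial Signal Structure in Iterated Bayesian Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of iterated learning in which combinatorial
    signal structure (duality of patterning) emerges from the interaction of a
    simplicity (minimum description length) prior and communicatively rational
    signal production. Agents maintain a full Bayesian posterior over an
    enumerated space of meaning-signal mappings, communicate in pairs with an
    ambiguity-penalised production rule, and are replaced by population
    turnover. Two transmission conditions (learning from the oldest agent
    versus learning from an agent mid-way through its lifespan) let users study
    how population structure modulates the rate at which combinatorial
    languages replace holistic ones. Includes batch runners, crossover-time
    statistics, trace input/output and figure-style plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
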