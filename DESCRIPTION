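Package: anttraffic
Title: Priority-Rule Traffic Simulation on Leaf-Cutting Ant Trails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-propelled particle simulation of bidirectional traffic on
    leaf-cutting ant foraging trails. Implements a one-dimensional narrow-trail
    model with stop/give-way priority rules and a cooperative-passage rule, and
    a two-dimensional wide-trail model with turn/give-way rules (plus a
    stop-rule control variant). Ants leave the nest and the leaf source by a
    Poisson process and are classed as outbound, inbound unladen, or inbound
    laden, each with its own speed and priority. The package records midpoint
    crossing events and provides a statistics layer that encodes crossing logs
    as signed sequences, decomposes them into alternating same-direction
    groups, and computes flow, group-size, laden-position, and lane-segregation
    (zone proportion) summaries, with seeded replicate batches and
    mean/s.d./min/max aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
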