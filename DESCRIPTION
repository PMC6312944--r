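Package: wardflow
Title: Stochastic Discrete-Event Simulation of Hospital Patient Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable discrete-event simulator of patients moving through
    the queued, capacity- and resource-constrained wards of a hospital.
    Patients arrive at an emergency department, follow random-walk pathways
    over a weighted ward-transition graph, and draw Poisson-distributed
    length-of-stay and treatment-need requirements per ward. Each ward is
    managed by configurable queue, resource-division and overflow policies.
    Completed runs are analysed for waiting-time target performance, bed
    occupancy, the realised patient-flow network with centrality statistics,
    journey summaries and operating costs. Ships an eight-ward, 220-bed
    default hospital and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
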