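Package: crushmi
Title: Crowd Evacuation Simulation and Mutual-Information Crush Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-dimensional social-forces crowd evacuation simulator with a
    passive, information-theoretic crush detector. Windowed pairwise mutual
    information over agent coordinates and headings serves as an order
    parameter whose collapse signals the onset of crowd turbulence and crush;
    the signal is validated against an explicit Newtonian contact-force
    monitor computed from the same simulation. Includes benchmark and
    multi-exit club scenarios with probabilistic exit-knowledge assignment and
    timed door closure, synthetic trajectory fixtures with known order
    structure, replicate ensemble runners, and Pearson correlation analysis of
    the mutual-information / force relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
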