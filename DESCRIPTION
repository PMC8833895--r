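Package: brewdfo
Title: Inverse Beer Recipe Design with Dispersive Flies Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovers beer recipes from target organoleptic properties
    ("reverse brewing"). Given an inventory of in-stock ingredients with
    physicochemical attributes and a target profile of five properties
    (alcohol by volume, bitterness, colour, original and final gravity),
    a dispersive flies optimiser searches the box of feasible ingredient
    amounts for recipes whose simulated properties match the target. A
    forward brewing simulator (extract-potential gravity, Tinseth
    bitterness, Morey colour) supplies the fitness function. The package
    also provides the accompanying analysis tool-set: reliability,
    efficiency and swarm-diversity measures, pairwise solution-distance
    matrices, K-means recipe-family clustering with a majority vote over
    cluster-validity indices, hierarchical linkage, and dynamic-target
    experiments in which the desired properties change during the run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
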