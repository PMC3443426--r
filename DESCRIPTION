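Package: qualsim
Title: Construction, Simulation and Dose-Response Analysis of Qualitative
    Boolean Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build qualitative ("bio-logic") regulatory network models from
    activator/inhibitor clauses, compile them to Boolean expressions, and
    simulate them synchronously under continuous extracellular stimuli
    expressed as %ON activity levels on a 0-100 scale. Provides sliding-window
    and attractor-based activity measurement, randomized-environment
    experiments with dose-response (input-output) curves, in-silico gain- and
    loss-of-function mutations, random network generation, and model exchange
    via a flat-text Boolean expression format and the SBML Level 3
    qualitative-models package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    xml2,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
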