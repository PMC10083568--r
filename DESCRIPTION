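Package: senhsr
Title: Titration Modelling of the Heat-Shock Response in Senescent Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay differential-equation modelling of HSPA1A regulation by
    HSF1 titration and CHIP-mediated turnover in early- and late-passage
    mesenchymal stem cells. Provides equilibration, heat-stress simulation,
    multi-start parameter fitting against immunofluorescence time courses,
    senescence perturbation and misfolded-protein burden metrics, together
    with chaperome protein-protein-interaction modularity analysis,
    module- and subset-level differential statistics, and synthetic data
    generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
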