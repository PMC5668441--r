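Package: hipscpop
Title: Populations of hiPSC-Derived Cardiomyocyte Models for LQT3 Drug
    Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation modelling of
    spontaneous action potentials in human induced pluripotent stem
    cell-derived cardiomyocytes (hiPSC-CMs), including a Hodgkin-Huxley
    late sodium current with a long QT syndrome type 3 (V1763M)
    gain-of-function variant. Provides experimentally calibrated
    populations of models, in-silico transfection and phenotype
    classification, and multichannel pore-block drug trials with
    action-potential biomarker readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
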