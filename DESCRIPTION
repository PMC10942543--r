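Package: vsmsim
Title: Sex-Specific Electrophysiology and Calcium Signaling in Arterial Smooth Muscle Myocytes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley-type model of mesenteric arterial smooth muscle
    myocytes with sex-specific (male/female) parameter sets. Simulates membrane
    potential and three-compartment calcium dynamics (cytosol, sarcoplasmic
    reticulum, junctional domain) with Goldman-Hodgkin-Katz currents, BK(Ca)
    spark-STOC coupling, stochastic Euler-Maruyama integration, a 1D
    gap-junction-coupled vessel cable, a five-parameter gating-rate fitting
    workflow, population-based regression sensitivity analysis, and
    drug-block/pressure protocols.
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
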