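Package: tdcsim
Title: Whole-Brain Network Modelling of Transcranial Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the effect of transcranial direct current stimulation
    (tDCS) on whole-brain activity with a structural-connectivity-coupled
    dynamic mean-field model. Cortical electric fields (normal component) are
    translated into a membrane-polarization term injected into the synaptic
    gating dynamics of stimulated regions; regional activity is converted to
    BOLD signals through a Balloon-Windkessel hemodynamic model. Includes the
    downstream analysis battery: static and sliding-window dynamic functional
    connectivity, weighted graph topology, resting-state-network aggregation,
    Kuramoto synchrony and metastability, complexity metrics (Hurst exponent,
    Lempel-Ziv complexity, permutation fuzzy entropy), and paired condition
    contrasts with false-discovery-rate control. Synthetic generators for
    parcellations, structural connectomes and bipolar field patterns allow
    fully in-silico studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    signal,
    pracma,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
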