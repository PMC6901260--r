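Package: txnfrap
Title: Stochastic Simulation and FRAP Analysis of Transcription-Site mRNA Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of RNA polymerase II transcription on an
    MS2-tagged tandem reporter gene array (initiation, elongation with stochastic
    pausing, stochastic termination, post-transcriptional transcript retention and
    positional intron depletion), with in-silico photobleaching to generate FRAP
    (fluorescence recovery after photobleaching) recovery curves and steady-state
    intron/exon FISH ratio snapshots. Includes the companion analysis pipeline:
    double normalization of raw FRAP traces, mono/bi-exponential recovery fitting
    with AIC model selection and mobile-fraction extraction, permutation-based
    recovery-curve comparison with Benjamini-Hochberg correction, retrieval of the
    transcript retention time by fitting the simulator to observed curves, and
    seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
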