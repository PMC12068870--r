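Package: epinoci
Title: Quantification of Epidermal Mechanosensation and Nociceptive
    Sensitization Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for larval Drosophila mechanonociception and
    epidermal calcium-imaging experiments. Computes ethogram summaries from
    annotated behavior event tables (response probabilities, 1-s binned
    behavior fractions, latencies, bout durations, post-stimulus
    persistence, cumulative response curves), two-stimulus sensitization
    statistics with exponential-decay recovery fitting, RNAi-screen
    potentiation indices with z-score hit calling, and fluorescence-trace
    metrics (baseline F0, F/F0 normalization, peak ratio, trapezoidal AUC,
    response duration, decay-constant fits, responder classification,
    ionomycin viability gating, store-operated calcium entry phase
    decomposition, and stretch dose-response recruitment). Includes seeded
    synthetic-data generators emulating each assay so every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
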