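Package: eegbp
Title: Coupling Analysis of Neonatal EEG and Arterial Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed linear and nonlinear coupling analysis between
    multichannel neonatal EEG and mean arterial pressure (MAP).
    Extracts 1 Hz EEG sub-band power features and a smoothed MAP series
    from raw recordings, quantifies their interaction per 30-minute
    window with Pearson correlation, Welch coherence, and adjusted
    mutual information (histogram mutual information corrected by its
    exact hypergeometric expectation), and measures directed coupling
    with the Kraskov-Stogbauer-Grassberger nearest-neighbour transfer
    entropy estimator using active-information-storage embedding
    selection. Per-window significance is assessed against shuffled
    surrogates, and per-subject median coupling is associated with an
    illness-severity score via Spearman rank correlation with bootstrap
    confidence intervals and Holm-Bonferroni correction. A synthetic
    data module generates EEG/BP recordings and cohorts with tunable
    coupling strength and direction so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
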