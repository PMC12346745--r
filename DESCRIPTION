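Package: ecgfusion
Title: Dual-Branch Convolutional Networks for 12-Lead ECG Arrhythmia
    Classification with Lead-Level Shapley Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and interprets dual-branch 1-D convolutional
    neural networks that classify 12-lead electrocardiograms into arrhythmia
    superclasses and subclasses while fusing patient demographics (age, sex)
    through a parallel dense branch.  Reads PTB-XL-style corpora (WFDB
    waveforms plus CSV metadata), materializes binary, 5-, 10- and 15-class
    diagnostic scenarios with fold-based train/validation/test splits,
    expands training sets with Gaussian-noise and gain augmentation, reports
    confusion matrices with micro- and macro-averaged metrics, and computes
    per-lead Shapley importances by exact coalition enumeration over the 12
    leads or by seeded permutation sampling.  A bundled synthetic-corpus
    generator with class-dependent, lead-localized signal structure makes
    every stage testable without downloading clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
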