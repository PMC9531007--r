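Package: cmpad
Title: Contextual Matrix Profile Anomaly Detection for Daily Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised anomaly detection for multivariate daily-activity
    time series from in-home passive infrared (PIR) movement sensors, aimed at
    flagging adverse health events (urinary tract infections, hospitalizations)
    in remotely monitored households. Implements the Contextual Matrix Profile
    (block-minimum z-normalized Euclidean distance between time segments), a
    multidimensional extension that averages the k+1 smallest per-feature
    distances per segment with automatic selection of k by knee detection,
    distance- and entropy-weighted score fusion (approximate and fuzzy
    entropy), sliding-window robust-z/IQR/quantile thresholding, soft-buffer
    recall evaluation against weak labels, digital-biomarker ranking, and a
    seeded synthetic household-movement simulator with injected infection-like
    and hospitalization-like episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
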