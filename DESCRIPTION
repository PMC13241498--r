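Package: resplock
Title: Respiration Phase, Pupil Size and Perceptual Reversals of Bistable Figures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studies linking respiration,
    pupil-linked arousal and spontaneous perceptual reversals of bistable
    figures. Provides respiration cycle segmentation with linear phase coding,
    pupillometry cleaning (blink interpolation, exponential detrending,
    low-pass filtering), event-locked phase-locking value (PLV) with a
    circular-shift surrogate null and maximum-statistic correction, the
    epoch-count-unbiased pairwise phase consistency (PPC), cluster-based
    permutation tests of event-locked traces against baseline, behavioural
    quality control with dominance-duration distribution fitting, and
    time-resolved linear mixed-model comparison of percept-stability
    predictors via AIC differences and Akaike weights. A synthetic-data
    generator with known ground truth makes every stage testable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    lme4,
    fitdistrplus,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
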