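Package: nestwatch
Title: Behavioural and Neural Analysis of Socially Transmitted Maternal Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing days-long home-cage recordings of mouse
    dams and co-housed virgin females as they acquire alloparental pup
    retrieval. Scores behavioural events from trajectories (nest crossings,
    chases, shepherding, time in nest, retrieval onset, ultrasonic
    distress-call bouts); quantifies event-aligned single-unit spike-train
    modulation with a shift-permutation null and Benjamini-Hochberg false
    discovery control; classifies optogenetically photo-tagged units;
    compares activated fractions between unit populations with exact tests,
    Koopman score confidence intervals for the relative risk, and log-rank
    comparisons of retrieval-onset curves; processes fibre-photometry traces
    (lock-in demodulation, dF/F, per-call and per-trial responses) and joint
    single-trial spike-calcium correlations. A synthetic cage-session
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
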