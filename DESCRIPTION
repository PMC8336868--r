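Package: miconn
Title: Mu-Suppression Scoring and ERP Brain-Network Analysis for Short-Term Motor-Imagery BCI Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short-term motor-imagery (MI) brain-computer-interface
    training EEG. Implements event-related desynchronization quantification via the
    Mu-suppression score with subject-specific Mu-band selection (multitaper band power,
    sliding 3 Hz frequency window), event-related-potential trial-block averaging, Pearson
    functional-connectivity brain networks with node, hemispheric and whole-brain
    graph indicators (weighted degree, regional degree, global transitivity on a
    binarized graph), and super-trial trend statistics (Welch t-tests, OLS slope fits).
    Includes a synthetic MI-EEG session generator with planted ERD, ERP templates and
    condition-dependent session trends for ground-truth validation, and readers/writers
    for EDF and a plain epochs-table format on the 19-channel 10-20 montage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tidyr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
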