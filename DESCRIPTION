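Package: pamgame
Title: Performance Accommodation Mechanisms in a Simulated Motor-Imagery BCI Game
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a motor-imagery brain-computer-interface
    (BCI) fishing game with performance accommodation mechanisms (PAMs), and an
    ordinal analysis toolkit for the ratings such experiments produce. The
    simulator comprises a synthetic-EEG generator with event-related
    desynchronization, an online decoder (band-pass, common spatial patterns,
    linear discriminant, dwell-threshold detection at 16 decisions per second),
    a deterministic fishing-game state machine, and an urn-model trial
    scheduler that targets 30% help and caps experienced control at 70%. The
    analysis side provides a from-scratch cumulative link mixed model (ordinal
    logit with subject random intercepts, Laplace-approximated maximum
    likelihood), likelihood-ratio tests, and AIC forward stepwise selection,
    together with a packaged per-participant study table the pipeline
    reproduces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
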