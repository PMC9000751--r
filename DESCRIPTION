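Package: grpmap
Title: Rank-Based Expression Profiling, Enrichment and Connectivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rank-based transcriptional profiling of treated versus
    control expression experiments. Computes gene rank profiles (GRP) of a
    sample set relative to a background expression compendium, treated-versus-
    control differential Z profiles with probe-to-gene collapse, a
    Kolmogorov-Smirnov-variant gene-set enrichment statistic with an analytic
    normal null and a Monte-Carlo calibrator for its constants, signed
    Fisher-exact connectivity scoring of up/down gene signatures against
    signature banks, transcription-factor co-expression profile (TFCEP)
    construction from expression compendia, and Stouffer combination of
    differential profiles. Includes a synthetic-data generator with recorded
    planted truths so the whole pipeline is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
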