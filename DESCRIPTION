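Package: soundenrich
Title: Individualized Sound-Enrichment Therapy Stimuli for Tinnitus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for audiogram-driven sound-enrichment therapy in
    hearing-loss-related tinnitus. Reads and validates pure-tone audiograms,
    locates the hearing-loss frequency region, screens tinnitus profiles
    against psychoacoustic eligibility criteria (45-55 dB HL threshold at
    the tinnitus pitch, positive residual inhibition, chronicity), and
    synthesizes individualized therapy sounds: Gaussian noise shaped by a
    loss-configuration spectral envelope with an extra emphasis band around
    the tinnitus pitch, plus a placebo variant confined to the
    normal-hearing range. Includes the phased listening schedule, spectral
    verification via Welch periodograms, WAV export, and a synthetic
    fixture generator for audiograms, profiles and screening cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
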