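Package: tfbscout
Title: Mining Transcription-Factor-Based Biosensors from Catabolic Gene Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate transcription-factor-based biosensors for a
    target metabolite. Given a reaction knowledge base, the package enumerates
    enzymatic chains that sequentially degrade the metabolite, screens bacterial
    genome feature tables for organisms encoding a chain as a compact
    co-oriented gene cluster (a putative catabolic operon), locates the nearest
    divergently oriented transcriptional regulator, and scores each
    regulator-operon pair by genomic proximity. Also provides Hill
    dose-response fitting and the closed-form 5-95 percent operational range
    used to characterize validated sensors, plus simulators for knowledge
    bases, annotated genomes with planted operon-regulator arrangements, and
    noisy dose-response data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    minpack.lm,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
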