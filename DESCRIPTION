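Package: retentostat
Title: Growth Energetics of Glucose-Limited Chemostat and Retentostat Cultures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative physiology toolkit for glucose-limited continuous
    cultivation at very low specific growth rates. Implements the Herbert-Pirt
    relation and chemostat steady-state algebra, mixing-vessel feed-profile
    design with exponentially declining feed glucose, forward simulation of
    retentostat biomass accumulation (with optional first-order cell death),
    least-squares estimation of the maintenance coefficient and death rate
    from biomass and viability time series, moving-window regression that
    resolves growth-rate-dependent maintenance energy and maximum biomass
    yield, storage-carbohydrate substrate accounting, and a seeded synthetic
    data generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
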