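Package: borealflux
Title: Trend and Attribution Analysis of Boreal Forest Carbon and Water Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-year eddy-covariance records from boreal
    coniferous forests: a synthetic half-hourly flux and meteorology generator
    with known ground truth, marginal-distribution-sampling gap filling,
    nighttime (Lloyd-Taylor) flux partitioning into gross primary productivity
    and ecosystem respiration, resource-use efficiency and phenology metrics,
    Theil-Sen and moving-window partial-correlation trend statistics, a
    big-leaf decomposition of flux changes into CO2-fertilization, structural
    and physiological terms, and a simplified multilayer sunlit/shaded
    Farquhar-Medlyn canopy model with a scenario engine for attributing flux
    trends to meteorology, ambient CO2, leaf area and leaf nitrogen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
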