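Package: nightheat
Title: Daytime and Nighttime Heatwave Indices and Case-Crossover Health Impact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds daytime and nighttime heatwave indices (HWIs) from daily
    maximum and minimum temperatures using climatological percentile
    thresholds, detects and classifies daytime- versus nighttime-accentuated
    heatwave events, assembles time-stratified case-crossover panels from
    daily health event counts, fits conditional quasi-Poisson regressions
    (linear, binary, natural-spline and single-lag exposure forms), tests
    heterogeneity between effect estimates with Bonferroni adjustment, and
    converts fitted coefficients into heatwave-attributable fractions and
    annual attributable numbers with Monte Carlo confidence intervals. A
    synthetic-data generator with known ground truth supports simulation
    studies and end-to-end testing.
License: MIT + file LICENSE
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
    readr,
    lubridate,
    ggplot2,
    generics,
    stats,
    splines
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
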