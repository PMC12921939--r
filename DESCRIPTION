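Package: perisim
Title: Simulated Perimetry Exams and Between-Device Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how a perimeter's dynamic range shapes the
    visual fields it measures. Models perimetric devices (background
    luminance, largest and smallest presentable luminance increments,
    display quantization, neutral-density filtering), generates the 68
    locations of the 10-2 test pattern, synthesizes ground-truth
    sensitivity fields with inherited-retinal-disease loss patterns
    (central, bull's-eye and concentric scotomas), simulates Bayesian ZEST
    threshold exams against a frequency-of-seeing observer, and quantifies
    between-device agreement with scale harmonization, range censoring,
    Deming errors-in-variables regression, Bland-Altman limits of
    agreement, and floor-detection contingency metrics. All results are
    tibbles; fitted objects provide tidy() and glance() methods and
    ggplot2-based autoplot() visualizations, including grayscale field
    plots.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
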