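Package: zibicc
Title: Rater Reliability for Bounded, Zero-Inflated Ratings via Bayesian
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates inter- and intra-rater reliability for bounded 0-100
    rating scales with excess zeros, as used when therapists score
    compensatory movements from video. Fits a zero-inflated beta
    mixed-effects model by MCMC (JAGS), derives intraclass correlation
    coefficients with 95% credible intervals from posterior variance
    components, classifies them on the Koo & Li scale, plans rater panels
    by Bonett's precision approach, and simulates realistic rating
    datasets with known reliability for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
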