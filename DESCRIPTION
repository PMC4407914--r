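Package: radburst
Title: Diversity and Disparity Through Time in Adaptive Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing early-burst scenarios in adaptive radiations
    from time-calibrated phylogenies and continuous traits. Simulates pure-birth
    and birth-death trees conditioned on crown age and extant richness, simulates
    Brownian-motion and Ornstein-Uhlenbeck trait evolution with time-windowed
    rate multipliers, computes disparity-through-time curves and the
    morphological disparity index against null envelopes, fits BM and OU models
    by maximum likelihood with AICc comparison across posterior tree samples,
    detects diversification-rate shifts on diversity trees by stepwise AICc
    search, and estimates per-interval Kendall-Moran diversification rates
    with simulation-based envelopes under incomplete-sampling schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
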