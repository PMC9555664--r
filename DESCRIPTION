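Package: eggsync
Title: Interspecific Synchrony and Environmental Buffering of Seabird
    Breeding Investment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify interspecific synchrony between two annual
    time series of breeding investment (mean egg volume), as used to study
    how anthropogenic food subsidies decouple sympatric seabird species
    from shared environmental forcing.  Provides egg-volume morphometrics
    (V = beta * L * W^2 with species-specific constants), a state-based
    Markov-chain synchrony index comparing observed state-occupancy
    entropy to a simulated independent-chains null (Phi_t = 1 -
    H_t/H_null), breakpoint cross-correlation, Gaussian GLMs of egg
    volume on species, synchrony and the winter North Atlantic
    Oscillation index with AICc selection and multimodel averaging, and a
    seeded synthetic-data generator that emulates a subsidy regime switch
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
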