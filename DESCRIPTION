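Package: culturesweep
Title: Cultural Selective Sweeps, Standing Variation and Evolutionary Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact and simulation-based analysis of cultural adaptation in
    finite populations. Builds birth-death (Moran-type) transition kernels
    for unbiased, payoff-biased and conformist/anti-conformist cultural
    transmission; computes fixation probabilities of a beneficial cultural
    variant arising de novo or present as standing variation, sojourn-time
    and occupancy distributions, and an infinite-sites trait frequency
    spectrum; quantifies the trade-off between foresight and directed
    innovation; and simulates cultural evolutionary rescue in a declining
    population, with matching mean-field recursions. Includes Monte-Carlo
    validation utilities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
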