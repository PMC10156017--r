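Package: aldnp
Title: Differential Divisive Normalization Models of the Drosophila Antennal Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates odor information processing in the Drosophila antennal
    lobe with differential Divisive Normalization Processors (DNPs). Provides
    synthetic odorant stimuli (concentration staircases, binding/dissociation
    identity vectors, affinity panels), feedback/feedforward and global
    (spatio-temporal) DNP dynamics with closed-form steady states, noisy
    Connor-Stevens spike generators with frequency-current inversion and
    limit-cycle extraction, single- and multi-channel antennal-lobe circuits
    with five presynaptic-inhibition architectures, PSTH estimation and
    steady/transient ON/OFF response decomposition, angular-distance objectives,
    and a two-step Latin-Hypercube + Differential-Evolution fitting framework
    with a pseudo-physiology module standing in for unavailable recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
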