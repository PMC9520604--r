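Package: critsig
Title: Signatures of Criticality in Spiking Networks and Thresholded Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a spiking system operates near a
    critical phase transition. Implements neuronal avalanche extraction,
    discrete truncated power-law fitting with model comparison, the
    crackling-noise exponent relation, avalanche shape collapse, Hurst
    exponents from windowed standard deviations, naive branching ratios,
    and stimulus-response mutual information. Includes a discrete-time
    sparse excitatory/inhibitory leaky integrate-and-fire network with
    pulse stimulation and configurable noise drives, plus thresholded
    random-walk null models (reflected coin flips, Ornstein-Uhlenbeck
    processes) that mimic criticality signatures without interactions,
    and experiment drivers that discriminate emergent from driven
    criticality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
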