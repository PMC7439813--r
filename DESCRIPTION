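Package: presynstab
Title: Presynaptic Inhibition as a Rapid Stabiliser of Plastic Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of GABA-B-mediated presynaptic inhibition acting as a fast
    multiplicative brake on recurrent excitation in cortical circuits. Provides
    a two-population mean-field model with closed-form steady states, linear
    stability analysis and the critical homeostatic timescale; a full
    excitatory-inhibitory rate network with BCM plasticity and a sliding
    threshold; a current-based leaky integrate-and-fire network with triplet
    STDP and metaplastic long-term depression; and experiment drivers for
    rate-versus-recurrence curves, critical-timescale scans, input-sensitivity
    analyses and single-neuron rate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
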