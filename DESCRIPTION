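Package: spikevar
Title: Decomposing Neural Spike-Count Variability into Spiking
    Irregularity and Rate Variability
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for parsing trial-to-trial neural spike-count variability
    into within-trial spiking irregularity (nPsi) and between-trial rate
    variability (nRV) via the asymptotic linearity of the Fano factor in the
    counting-window width. Provides simulators for simple and doubly
    stochastic renewal point processes with time-varying rate and shape
    schedules and perturbations (bursting, rate noise, rate switching),
    Fano-factor-asymptote and sub-bin (Vinci-style) estimators with an
    empirical ground-truth oracle, CV2-based estimation of point-process
    variability, VarCE as a comparator, ISI-threshold burst detection,
    population controls (response-polarity clustering, mean matching), and
    balanced excitatory/inhibitory leaky integrate-and-fire network
    experiments linking presynaptic correlation structure to postsynaptic
    variability components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
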