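Package: sefron
Title: Spiking Neural Network Classification with Time-Varying Synaptic Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class classification of tabular biomedical features with a
    single leaky integrate-and-fire (LIF) output neuron whose synaptic weights
    are time-varying efficacy functions (SEFRON). Analog features are turned
    into presynaptic spike times by Gaussian receptive-field population
    encoding; learning accumulates Gaussian-modulated weight changes derived
    from a normalized spike-timing-dependent plasticity (STDP) rule; the
    output firing time is decoded into a class by a temporal boundary.
    Includes max- and min-max normalization, a synthetic-data generator that
    emulates imbalanced clinical voice-feature datasets, stratified K-fold and
    percentage-split evaluation with seven figures of merit (including Gmean
    and Matthews correlation), hyperparameter sweeps, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
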