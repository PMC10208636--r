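Package: lfposc
Title: Oscillatory Analysis of Hippocampal Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: State-resolved spectral parametrization, transient oscillation
    bout detection, cross-frequency coupling with surrogate statistics,
    sharp-wave-ripple detection, spike-field coherence via pairwise phase
    consistency, and spike-autocorrelogram theta-rhythmicity indexing for
    continuous extracellular recordings, together with a synthetic session
    generator that emulates state-dependent hippocampal LFP structure so the
    whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
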