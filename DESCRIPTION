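Package: habpipe
Title: Trial-Aligned Analysis of Fiber Photometry and Single-Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-related analysis of fiber-photometry calcium signals and
    sorted single-unit recordings from behaving animals. Computes dF/F
    event-related fluorescence aligned to behavioural events, peri-event time
    histograms with Gaussian smoothing and z-standardization, multivariate
    permutation tests with max-|T| family-wise correction, sliding-window
    ROC/AUC activation and selectivity profiles, optogenetic-tagging
    identification (waveform correlation, evoked latency/reliability, and a
    bootstrap latency test), and PCA plus complete-linkage clustering of
    response profiles into pure-inhibition and inhibition-then-excitation
    types. Includes a synthetic-session generator emulating GCaMP transients,
    conditioned spiking profiles, light-evoked spikes, and locomotion so that
    every stage of the pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    rhdf5,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
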