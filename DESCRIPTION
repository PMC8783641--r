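Package: lfpkit
Title: Laminar Hippocampal LFP Analysis: Sharp-Wave Ripples, Theta-Gamma
    Coupling, and Current Source Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel laminar local field
    potential (LFP) recordings from the hippocampus. Detects immobility
    periods, sharp-wave ripples, fast ripples, and interictal discharges
    from envelope thresholds; computes Morlet wavelet time-frequency maps,
    relative power spectra, and laminar theta power/phase profiles;
    extracts theta cycles with linear phase interpolation and quantifies
    gamma amplitude by theta phase on LFP and current-source-density
    signals; computes the theta-gamma modulation index; and aggregates
    session summaries with group comparisons. Ships a seeded synthetic
    laminar-LFP generator with a ground-truth event manifest so every
    stage is verifiable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
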