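Package: beatfield
Title: Temporal-Interference Stimulation Field Modelling and
    Stimulation-Locked Physiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models transcranial temporal-interference stimulation (tTIS)
    fields in simple volume conductors and analyses stimulation-locked
    physiology. Provides a finite-volume quasi-static current-flow solver
    for a 2-D disk tissue phantom and a layered ellipsoidal head, lead-field
    superposition for arbitrary injection patterns, computation of the
    beat-frequency envelope-modulation amplitude 2*min(|E1|,|E2|) with tACS
    comparison maps, current-ratio steering sweeps and focality summaries,
    an in-silico replica of a dipole-probe phantom scan with time-domain
    envelope extraction, a synthetic generator for fibre-photometry and
    pupil-position recordings locked to stimulation epochs, and the
    corresponding trace-analysis pipeline (isosbestic correction, dF/F,
    smoothing, resampling, pupil-to-angle conversion, windowed signed-rank
    statistics and entrainment spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
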