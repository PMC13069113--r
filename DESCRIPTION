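Package: vibci
Title: Visual-Imagery SSVEP Brain-Computer Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a gaze-independent
    brain-computer interface driven by visual imagery of flickering
    stimuli. Generates protocol-faithful synthetic multichannel EEG with
    steady-state visually evoked potential (SSVEP) and imagined-flicker
    responses over 1/f background activity; applies the offline filter
    chain (60 Hz low-pass, 48-52 Hz notch, 3-36 Hz Butterworth band-pass)
    and epoch extraction; estimates Welch and high-resolution
    periodogram power spectral densities; scores candidate stimulation
    frequencies by a peak-sharpness statistic and selects a
    subject-specific frequency couple; trains and evaluates a 3-class
    linear support vector machine under temporal cross-validation; and
    reproduces the statistical evaluation (adjusted-Wald chance-level
    bounds for k-class classifiers, accuracy summaries, Welch's t-test)
    against bundled per-subject reference accuracy tables. Reads and
    writes recordings as EDF+ or CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
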