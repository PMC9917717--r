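Package: hypercoh
Title: Wavelet Coherence Analysis of Dyadic fNIRS Hyperscanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for naturalistic two-person (hyperscanning)
    functional near-infrared spectroscopy. Converts dual-wavelength optical
    density to hemoglobin concentration changes (modified Beer-Lambert law),
    separates cortical from systemic hemodynamics (hemodynamic modality
    separation), pre-whitens with autoregressive filters, and estimates
    between- and within-brain synchrony with Morlet wavelet transform
    coherence on a 1/10-octave frequency grid with cone-of-influence
    masking. Provides group-level condition contrasts with Storey's pFDR
    q-values, automated classification of face-up events from head-pose
    pitch traces, event-related gamma/log-link generalized linear models
    linking coherence time courses to social behaviors, and a synthetic-data
    generator for dyadic recordings with controllable event-locked coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    jsonlite,
    optparse
Config/testthat/edition: 3
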