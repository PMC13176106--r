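Package: ivsi
Title: Isovolumic Relaxation Strain Imaging for Murine Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for speckle-tracking echocardiography strain
    traces with a focus on the isovolumic relaxation time (IVRT) window.
    Reads per-segment strain, strain-rate and velocity exports together with
    valve-event annotations, applies low-pass Butterworth smoothing and
    numerical differentiation, and extracts IVRT-windowed extrema metrics,
    chiefly the minimal acceleration of the radial strain rate, an early
    marker of active diastolic dysfunction. Includes pressure-trace
    hemodynamics (dP/dt extrema, Weiss tau), conventional echocardiographic
    ratios, a statistical layer (Welch tests, linear mixed-effects models
    with Satterthwaite degrees of freedom, Benjamini-Hochberg FDR, agreement
    statistics, a priori power analysis), and a parametric murine
    cardiac-cycle simulator for end-to-end validation without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
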