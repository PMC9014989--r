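Package: flightload
Title: Synthetic Multitasking Workload Studies with fNIRS and Heart-Rate Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the four-subtask simulated-flight multitasking paradigm
    (compensatory tracking, meter monitoring, emergency handling, and a
    residual-capacity numeral task) with a limited-capacity synthetic operator,
    generates load-dependent physiological signals (RR-interval tachograms and
    eight-channel two-wavelength fNIRS optical densities with known ground-truth
    activation), and runs the full analysis chain: behavioral performance
    scoring, weighted NASA-TLX workload scores, time- and frequency-domain
    heart-rate-variability features, modified Beer-Lambert conversion, wavelet
    denoising, HRF-precolored GLM activation estimates, and one-way
    repeated-measures ANOVA with Bonferroni post-hocs and Pearson correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
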