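Package: fpvs
Title: Frequency-Tagging Analysis of Fast Periodic Visual Stimulation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for oddball frequency-tagging (fast periodic visual
    stimulation, FPVS) EEG experiments: a ground-truthed synthetic EEG
    generator, BrainVision file input/output, the standard preprocessing
    chain (average re-reference, bad-channel interpolation, zero-phase
    band-pass filtering, epoching, ICA-based ocular correction,
    integer-cycle cropping), single-sided amplitude spectra with
    neighbouring-bin baseline subtraction and z-score harmonic selection,
    region-of-interest summaries with a collapsed-localizer electrode
    choice, and balanced mixed-design repeated-measures ANOVA with
    Mauchly's sphericity test, Greenhouse-Geisser correction, follow-up
    t-tests and standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
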