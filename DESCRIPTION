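Package: cilisten
Title: EEG and Psychophysics Pipeline for Longitudinal Cochlear-Implant
    Listening Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify auditory adaptation to a cochlear implant (CI)
    from electroencephalography (EEG) and adaptive psychophysics. Implements
    synthesis of realistic multichannel EEG sessions (auditory steady-state
    responses, onset potentials, CI electrical artifacts, attention-modulated
    alpha oscillations) and simulated psychometric observers; preprocessing
    with zero-phase filtering, epoching, amplitude- and percentile-based trial
    rejection, PCA/ICA component decomposition with automated CI-artifact
    classification, spherical-spline channel interpolation and average
    referencing; auditory steady-state response quantification (global field
    power, evoked spectra, intertrial phase coherence); hemispheric alpha-power
    lateralization indices over occipito-parietal electrode sets; 2-down-1-up
    and 1-down-1-up adaptive staircases with threshold estimators and CI
    benefit; and the accompanying inferential statistics (sign-flip
    permutation t tests, repeated-measures ANOVA with Greenhouse-Geisser
    correction, Spearman reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ica,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
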