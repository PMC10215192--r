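Package: eogcoupling
Title: EEG-EOG Coupling Analysis for Automatic Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how electroencephalogram (EEG) content coupled
    into the electrooculogram (EOG) affects automatic sleep staging. Provides a
    synthetic polysomnography generator with known latent sources and mixing,
    standard signal conditioning (notch, band-pass, resampling, epoching),
    second-order blind identification (SOBI) by joint approximate
    diagonalization of lagged covariance matrices with ocular-component
    removal, correlation-calibrated construction of EEG-coupled EOG signals,
    a two-scale convolutional + bidirectional GRU sleep-stage classifier, and
    a leave-one-subject-out evaluation protocol with a chi-square feature
    significance analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
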