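Package: bistableEEG
Title: Event-Locked EEG Analysis of Bistable Perception with Field
    Dependence-Independence Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel EEG recorded during a
    bistable-perception (ambiguous figure) task. Provides a synthetic
    experiment generator with controllable ground-truth effects (injected
    ERP components, alpha/gamma band-power modulations, group-level
    differences), Hamming-windowed FIR band-pass preprocessing,
    event-locked epoch extraction with prestimulus baseline correction,
    twelve ERP and Welch band-power features over 24 electrodes and six
    channel groups, Hidden Figures Test scoring with Field
    Dependent/Neutral/Independent classification and Cronbach's alpha,
    and the paired/two-sample t-test comparison matrix with
    Holm-Bonferroni familywise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
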