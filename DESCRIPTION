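Package: nleeg
Title: Nonlinear EEG Features and Group Statistics for Emotional
    Auditory Perception Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for band-limited nonlinear analysis of
    multichannel resting and stimulus-locked EEG: EDF and delimited-table
    input/output, zero-phase Butterworth band filtering with amplitude-based
    artifact rejection, five time-domain/nonlinear features (Higuchi fractal
    dimension, Hilbert-envelope mean frequency in wideband and alpha bands,
    envelope coefficient of variation, Hjorth mobility and complexity),
    power spectral density integrated over unit-width 2-20 Hz bins,
    between-group and stimulation-versus-rest contrasts with Bonferroni and
    Tukey adjustment, and PSD/rating correlation maps. Ships a seeded
    synthetic-cohort generator (1/f colored noise, amplitude-modulated alpha,
    group-specific band boosts, coupled subjective ratings) so the whole
    pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
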