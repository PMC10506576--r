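Package: pitchshift
Title: Simulated Hearing Loss, Missing-Fundamental Pitch Shift, and the Shift Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-alternative forced-choice psychoacoustics study of
    pitch shifts under simulated hearing loss. Builds band-limited harmonic
    complex-tone stimuli (eight tone pairs with low-frequency cutoffs at 250,
    500, 750 or 1000 Hz and high-frequency cutoffs at 1300 or 1600 Hz, plus
    eight band-limited versions of a thirteen-note melody), renders them to
    16-bit/44.1 kHz WAV audio, simulates cohorts of listeners under an explicit
    fundamental-frequency-versus-spectral logistic response model, computes
    per-participant Shift Index scores and ambiguous-response rates, and runs
    the paired nonparametric comparison schedule (exact and approximate
    Wilcoxon signed-rank tests, McNemar tests) over the eight conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
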