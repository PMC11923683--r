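Package: phonoid
Title: Golden-Ratio Stimulus Synthesis and Proteinoid Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing proteinoid microsphere ensembles with
    Fibonacci- and Golden-Ratio-structured electrical and audio stimuli.
    Generates inverse-Fibonacci and phi-decay voltage sequences, Fibonacci
    tone banks and phi-harmonic fractal soundscapes; models the proteinoid's
    capacitive (RC) electrical response and impedance; computes the full
    input/output metric set (SNR, Welch power spectral density,
    cross-correlation, RMSE/MAE/PSNR, frequency and impulse response,
    bispectrum, spectrogram); estimates histogram-based mutual information,
    band-limited transfer entropy, coherence and transfer efficiency;
    simulates signal-modulated Brownian motion of microspheres in a box;
    and analyses particle trajectories (mean squared displacement,
    exponential and power-law fits, diffusion coefficients, step-size
    ratios) and microsphere size distributions (normality battery,
    pairwise size ratios against phi). A seeded synthetic-data generator
    emulates the recorded data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
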