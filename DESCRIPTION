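Package: rifadecay
Title: mRNA Decay Rates, Differential Stability and RNase E Kinetics from
    Transcription-Shutoff Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-transcript mRNA degradation rate constants from
    rifampicin time-course microarray intensities: rank-invariant probeset
    normalization between strains, median-of-probes summarization, pooled
    log-linear regression with a coefficient-of-variation reliability filter,
    and conversion of rate constants to half-lives. Tests differential RNA
    stability between two strains with a time-by-strain interaction model and
    Benjamini-Hochberg false discovery control, compares half-life
    distributions by Kolmogorov-Smirnov tests, and scores functional-term
    over-representation with the hypergeometric test. Companion estimators
    cover bulk chemical and functional mRNA stability with stable-RNA baseline
    subtraction, generic exponential decay fits for northern and pulse-chase
    series, and Michaelis-Menten fitting of ribonuclease cleavage kinetics.
    Seeded simulators generate every input class with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
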