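Package: afmp
Title: Matching-Pursuit Analysis of Atrial Activity for Cardioversion Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts maintenance of sinus rhythm after direct-current electric
    cardioversion of persistent atrial fibrillation from a single-lead ECG.
    Extracts the atrial activity by average beat subtraction with
    correlation-gated segment selection and kurtosis-based excerpt picking,
    decomposes it by greedy matching pursuit over a shift-invariant dictionary
    of Coiflet-1 and Symlet-2 wavelet atoms at six dyadic scales, derives
    thirteen occupancy and decay features, screens them with the Mann-Whitney
    U test, and classifies AF-Free versus AF-Relapse with quadratic
    discriminant analysis under leave-one-out cross-validation. Includes a
    seeded synthetic AF-ECG generator with known ground-truth fibrillatory
    waves, a dominant atrial fibrillatory rate (AFR) comparator, and an
    end-to-end pipeline with plotting and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
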