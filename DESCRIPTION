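Package: aquilaheart
Title: Hybrid LSTM-Quantum Neural Network Heart-Disease Classification with
    Self-Improved Aquila Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for tabular cardiovascular-risk classification built around
    a metaheuristic wrapper pipeline: readers and preprocessing for the UCI
    heart-disease table dialects, statistical feature extraction (central
    tendency, dispersion, qualitative variation and symmetric uncertainty),
    a Self-Improved Aquila Optimizer (Levy-flight metaheuristic with a
    logistic-map chaotic step and arithmetic crossover) used both for wrapper
    feature selection and for tuning LSTM gate weights, a from-scratch LSTM
    and a multi-level-sigmoid quantum neural network whose averaged
    probabilities form the hybrid predictor, a full confusion-matrix metric
    report, and a synthetic clinical-table generator with planted signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
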