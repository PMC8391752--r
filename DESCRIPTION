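Package: fldcast
Title: Current- and Next-Visit Prediction of Fatty Liver Disease from
    Longitudinal Health-Checkup Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling fatty liver disease (FLD) risk from
    irregular longitudinal health-checkup records: a synthetic cohort
    generator with known ground truth, preprocessing (drop rules, mean/mode
    imputation, questionnaire consolidation, z-score normalisation),
    wrapper feature selection (one-pass ranking and sequential forward
    selection) with expert-agreement statistics (intersection-over-union
    and coverage), a multi-classifier current-visit prediction harness with
    training-window sweeps and age-split analyses, irregular-visit sequence
    encodings for next-visit prediction (monthly interpolated fixed-interval
    windows and variable-interval encodings with time-span inputs), compact
    recurrent sequence classifiers trained by backpropagation through time,
    majority and persistence baselines, and error-reduction-rate reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
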