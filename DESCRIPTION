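Package: mpapnn
Title: Marine Predators Algorithm Training for Probabilistic Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid classifier that tunes the pattern weights and class
    biases of a Parzen-window probabilistic neural network (PNN) with the
    Marine Predators Algorithm (MPA), a population metaheuristic mixing
    Levy-flight and Brownian steps across three velocity-ratio phases with
    elite memory and a FADs stagnation perturbation. Includes the full
    evaluation harness used in the metaheuristic-PNN literature: stratified
    hold-out and repeated stratified k-fold protocols, confusion-matrix
    metric reports, a statistical comparison battery (Wilcoxon signed-rank,
    Holm-Bonferroni step-down, BCa bootstrap intervals, Cohen's d, Levene's
    test, rank and linear correlation), a synthetic-data generator that
    mirrors the shapes of the 11 UCI benchmark datasets, and a seeded
    multi-run benchmark driver with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    boot,
    car,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
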