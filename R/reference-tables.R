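# Published reference results from the MPA-PNN benchmark study on 11 UCI
# datasets, shipped as constants so the package's metric arithmetic and
# correlation analyses can be validated against them offline.

#' Published hold-out confusion matrices for PNN and MPA-PNN
#'
#' Per-dataset TP/FP/TN/FN counts from the published 70/30 hold-out
#' benchmark, together with the accuracy (percent) reported alongside
#' them. Two MPA-PNN rows (LD and Heart) whose counts do not sum to the
#' stated test-set sizes are flagged `consistent = FALSE` and are
#' excluded from consistency checks.
#'
#' @return A tibble with columns `dataset`, `method`, `tp`, `fp`, `tn`,
#'   `fn`, `reported_accuracy`, `consistent`.
#' @export
reference_confusions <- function() {
  out <- tibble::tribble(
    ~dataset,    ~method,    ~tp, ~fp, ~tn, ~fn, ~reported_accuracy,
    "PID",       "pnn",       35,  28,  90,  39, 65.104,
    "PID",       "mpa_pnn",   42,  20, 122,   8, 85.416,
    "HSS",       "pnn",       44,  12,   6,  15, 64.935,
    "HSS",       "mpa_pnn",   52,   5,  15,   5, 87.012,
    "AP",        "pnn",       23,   1,   1,   2, 88.889,
    "AP",        "mpa_pnn",   23,   1,   2,   1, 92.592,
    "BC",        "pnn",       14,   9,  36,  13, 69.444,
    "BC",        "mpa_pnn",   19,   3,  48,   2, 93.055,
    "LD",        "pnn",       18,  15,  34,  19, 60.465,
    "LD",        "mpa_pnn",   33,   3,  48,   1, 94.860,
    "Heart",     "pnn",       27,   5,  23,  13, 73.529,
    "Heart",     "mpa_pnn",   30,   0,  24,  12, 81.818,
    "GCD",       "pnn",      133,  46,  39,  32, 68.800,
    "GCD",       "mpa_pnn",  166,  13,  45,  26, 84.400,
    "Parkinson", "pnn",       38,   1,   6,   4, 89.796,
    "Parkinson", "mpa_pnn",   40,   1,   6,   2, 93.877,
    "SPECTF",    "pnn",       49,   4,   5,   9, 80.597,
    "SPECTF",    "mpa_pnn",   48,   3,  14,   2, 92.537,
    "ACA",       "pnn",       60,  14,  84,  15, 83.237,
    "ACA",       "mpa_pnn",   71,   4,  95,   3, 95.953,
    "Fourclass", "pnn",       78,   0, 138,   0, 100.000,
    "Fourclass", "mpa_pnn",   78,   0, 138,   0, 100.000
  )
  out$consistent <- !(out$method == "mpa_pnn" & out$dataset %in% c("LD", "Heart"))
  out
}

#' Published hold-out accuracies for all five methods
#'
#' Per-dataset accuracy (percent) of PNN, MPA-PNN and the three published
#' comparator hybrids (CHIO-PNN, ABO-PNN, B-HC-PNN), whose numbers are
#' treated as constants from their source publications.
#'
#' @return A tibble with `dataset` and one column per method.
#' @export
reference_accuracies <- function() {
  tibble::tribble(
    ~dataset,     ~pnn,   ~mpa_pnn, ~chio_pnn, ~abo_pnn, ~bhc_pnn,
    "PID",       65.104,  85.416,   83.850,    83.330,   81.250,
    "HSS",       64.935,  87.012,   85.410,    84.420,   85.720,
    "AP",        88.889,  92.592,   96.760,    96.300,   96.300,
    "BC",        69.444,  93.055,   90.020,    84.720,   84.720,
    "LD",        60.465,  94.860,   91.860,    84.880,   93.020,
    "Heart",     73.529,  81.818,   82.350,    82.350,   86.760,
    "GCD",       68.800,  84.400,   83.600,    82.800,   80.800,
    "Parkinson", 89.796,  93.877,   91.830,    95.920,   91.840,
    "SPECTF",    80.597,  92.537,   94.020,    89.550,   93.040,
    "ACA",       83.237,  95.953,   95.790,    94.800,   93.060,
    "Fourclass", 100.000, 100.000,  100.000,   100.000,  100.000
  )
}

#' Published dimensionality-sensitivity columns
#'
#' Feature count `d` and hold-out accuracy gain `delta` (MPA-PNN minus
#' PNN, percentage points) per benchmark dataset — the inputs of the
#' published rank/linear correlation analysis.
#'
#' @return A tibble with `dataset`, `d`, `delta`.
#' @export
reference_dimensionality <- function() {
  tibble::tribble(
    ~dataset,     ~d, ~delta,
    "Fourclass",   2,  0.00,
    "HSS",         3, 22.10,
    "LD",          6, 34.80,
    "AP",          7,  3.70,
    "PID",         8, 20.30,
    "BC",         10, 23.70,
    "Heart",      13,  8.30,
    "ACA",        14, 12.80,
    "GCD",        20, 15.60,
    "Parkinson",  23,  4.10,
    "SPECTF",     45, 11.90
  )
}
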