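fit_method <- function(method, train, sigma, config, seed, mode, rs_budget) {
  switch(
    method,
    pnn = pnn(train, sigma = sigma),
    mpa_pnn = {
      cfg <- config
      cfg$seed <- as.integer(seed)
      train_mpa_pnn(train, sigma = sigma, config = cfg, mode = mode)
    },
    random_search = train_random_search(train, sigma = sigma,
                                        budget = rs_budget, seed = seed,
                                        mode = mode),
    stop("Unknown method: ", method, call. = FALSE)
  )
}

evaluate_fit <- function(fit, test, dataset, method, seed, fold = NA_integer_) {
  model <- if (inherits(fit, "mpa_pnn")) fit$model else fit
  pred <- predict(model, test)
  truth <- test$label
  classes <- model$classes
  binary <- length(classes) == 2
  averaging <- if (binary) "positive_class" else "macro"
  scores <- as.matrix(pred[paste0(".score_", classes)])
  colnames(scores) <- classes
  positive <- if (binary) classes[length(classes)] else NULL
  report <- suppressWarnings(
    metric_report(truth, pred$.pred_class,
                  scores = if (binary) scores[, positive] else scores,
                  positive = positive, averaging = averaging)
  )
  cm <- if (binary) {
    confusion(truth, pred$.pred_class, positive = positive)
  } else {
    tibble::tibble(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
                   fn = NA_integer_, positive = NA_character_)
  }
  dplyr::bind_cols(
    tibble::tibble(dataset = dataset, method = method, seed = seed,
                   fold = fold),
    cm[c("tp", "fp", "tn", "fn")],
    report[c("accuracy", "precision", "recall", "f1", "auc")],
    tibble::tibble(
      train_fitness = if (inherits(fit, "mpa_pnn")) fit$best_fitness else NA_real_,
      baseline_fitness = if (inherits(fit, "mpa_pnn")) fit$baseline_fitness else NA_real_,
      evaluations = if (inherits(fit, "mpa_pnn")) fit$evaluations_used else NA_real_
    )
  )
}

#' Seeded multi-run benchmark on one dataset
#'
#' For every run seed the dataset is split per the chosen protocol
#' (stratified 70/30 hold-out, or stratified k-fold where each fold
#' serves as the test set once per repetition), features are min-max
#' normalized with training-derived parameters, every requested method is
#' trained on the training part and scored on the test part, and a tidy
#' row of confusion counts and metrics is appended. Fully deterministic
#' given the seeds.
#'
#' @param data Dataset tibble (features + `label`).
#' @param dataset_name Name recorded in the output rows.
#' @param methods Any of `"pnn"`, `"mpa_pnn"`, `"random_search"`.
#' @param protocol `"holdout"` (default) or `"repeated_kfold"`.
#' @param run_seeds One seed per run (hold-out) or per repetition
#'   (k-fold); default `1:30` mirroring the published protocol.
#' @param sigma PNN bandwidth.
#' @param config [mpa_config()] template for the MPA runs (its seed is
#'   replaced by each run seed).
#' @param mode Parameter encoding for the trained methods.
#' @param fraction Training fraction for the hold-out protocol.
#' @param k Folds for the k-fold protocol.
#' @param rs_budget Evaluation budget for `"random_search"`; default
#'   matches the MPA budget (N + 2 N t_max).
#' @param out_dir Optional directory: writes `runs.csv`,
#'   `aggregate.json` and per-run convergence CSVs.
#' @param label_col Name of the label column.
#' @return A tibble of class `benchmark_report`, one row per method x
#'   run (x fold for k-fold), with attribute `aggregate` (per-method
#'   mean/sd tibble).
#' @export
run_benchmark <- function(data, dataset_name = "dataset",
                          methods = c("pnn", "mpa_pnn"),
                          protocol = c("holdout", "repeated_kfold"),
                          run_seeds = 1:30,
                          sigma = 0.1,
                          config = mpa_config(),
                          mode = "pattern_bias",
                          fraction = 0.7,
                          k = 5,
                          rs_budget = NULL,
                          out_dir = NULL,
                          label_col = "label") {
  protocol <- match.arg(protocol)
  methods <- match.arg(methods, c("pnn", "mpa_pnn", "random_search"),
                       several.ok = TRUE)
  if (!is.data.frame(data) || !label_col %in% names(data)) {
    stop("`data` must be a data frame with a `", label_col, "` column.",
         call. = FALSE)
  }
  if (is.null(rs_budget)) {
    rs_budget <- config$population_size * (1 + 2 * config$max_iterations)
  }
  traces <- list()

  one_split <- function(train, test, seed, fold = NA_integer_) {
    norm <- min_max_normalize(train, test, label_col)
    purrr::map_dfr(methods, function(m) {
      fit <- fit_method(m, norm$train, sigma, config, seed, mode, rs_budget)
      if (inherits(fit, "mpa_pnn")) {
        traces[[paste(m, seed, fold, sep = "_")]] <<- fit$trace
      }
      evaluate_fit(fit, norm$test, dataset_name, m, seed, fold)
    })
  }

  rows <- if (protocol == "holdout") {
    purrr::map_dfr(run_seeds, function(s) {
      plan <- stratified_holdout(data, fraction = fraction, seed = s,
                                 label_col = label_col)
      one_split(data[plan$train_indices, ], data[plan$test_indices, ], s)
    })
  } else {
    plan <- repeated_stratified_kfold(data, k = k,
                                      repetitions = length(run_seeds),
                                      seeds = run_seeds,
                                      label_col = label_col)
    purrr::map_dfr(seq_along(run_seeds), function(r) {
      assignment <- plan$folds[[r]]
      purrr::map_dfr(seq_len(k), function(fold) {
        one_split(data[assignment != fold, ], data[assignment == fold, ],
                  run_seeds[r], fold)
      })
    })
  }

  aggregate <- rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      runs = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      mean_f1 = mean(.data$f1),
      mean_auc = mean(.data$auc),
      .groups = "drop"
    )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(rows, file.path(out_dir, "runs.csv"))
    jsonlite::write_json(
      list(dataset = dataset_name, protocol = protocol,
           aggregate = aggregate),
      file.path(out_dir, "aggregate.json"),
      digits = NA, auto_unbox = TRUE
    )
    for (nm in names(traces)) {
      readr::write_csv(traces[[nm]],
                       file.path(out_dir, paste0("trace_", nm, ".csv")))
    }
  }

  attr(rows, "aggregate") <- aggregate
  attr(rows, "protocol") <- protocol
  class(rows) <- c("benchmark_report", class(rows))
  rows
}

#' Benchmark the full synthetic suite
#'
#' Runs [run_benchmark()] over every dataset of [make_table2_suite()].
#'
#' @param master_seed Seed for the suite generator.
#' @param run_seeds Seeds for the per-dataset runs.
#' @param config [mpa_config()] template.
#' @param methods,sigma,protocol,... Passed to [run_benchmark()].
#' @return A `benchmark_report` tibble covering all datasets.
#' @export
run_suite_benchmark <- function(master_seed = 0, run_seeds = 1:5,
                                config = mpa_config(max_iterations = 30),
                                methods = c("pnn", "mpa_pnn"),
                                sigma = 0.1,
                                protocol = "holdout", ...) {
  suite <- make_table2_suite(master_seed)
  rows <- purrr::imap_dfr(suite, function(data, nm) {
    run_benchmark(data, dataset_name = nm, methods = methods,
                  protocol = protocol, run_seeds = run_seeds,
                  sigma = sigma, config = config, ...)
  })
  class(rows) <- c("benchmark_report", class(rows))
  rows
}

#' Statistical comparison of two benchmark reports
#'
#' Pairs the per-run accuracies of two reports on matched dataset/seed
#' (/fold) keys and runs the full comparison battery per dataset:
#' Wilcoxon signed-rank p, Cohen's d, BCa bootstrap CI of the mean
#' accuracy difference, and Levene's p for equality of run variances.
#' Across datasets, the Wilcoxon p-values enter a Holm-Bonferroni
#' step-down table.
#'
#' @param report_a,report_b `benchmark_report` tibbles (or single-method
#'   subsets of one report) with matched datasets and seeds.
#' @param alpha Family-wise level for the Holm table.
#' @param bootstrap_B Resamples for the BCa intervals, default 10000.
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `method_comparison`: `per_dataset` tibble
#'   (`dataset`, `mean_difference`, `wilcoxon_p`, `cohens_d`, `ci_lower`,
#'   `ci_upper`, `levene_p`), `holm` (a [holm_bonferroni()] table over
#'   the per-dataset p-values), `alpha`.
#' @export
compare_methods <- function(report_a, report_b, alpha = 0.05,
                            bootstrap_B = 10000, seed = 0) {
  key <- function(df) paste(df$dataset, df$seed, df$fold, sep = "|")
  a <- dplyr::arrange(tibble::as_tibble(report_a), .data$dataset, .data$seed, .data$fold)
  b <- dplyr::arrange(tibble::as_tibble(report_b), .data$dataset, .data$seed, .data$fold)
  if (nrow(a) != nrow(b) || !all(key(a) == key(b))) {
    stop("Reports do not share matched dataset/seed/fold runs.", call. = FALSE)
  }
  per_dataset <- purrr::map_dfr(unique(a$dataset), function(ds) {
    xa <- a$accuracy[a$dataset == ds]
    xb <- b$accuracy[b$dataset == ds]
    diffs <- xa - xb
    wp <- if (all(diffs == 0)) 1 else wilcoxon_signed_rank(xa, xb)$p_value
    ci <- bca_bootstrap_ci(diffs, statistic = mean, B = bootstrap_B,
                           seed = seed)
    lev <- levene_test(list(xa, xb))
    # a constant nonzero difference has no spread: flag as signed infinity
    d_eff <- if (stats::sd(diffs) == 0 && mean(diffs) != 0) {
      sign(mean(diffs)) * Inf
    } else {
      cohens_d(xa, xb)
    }
    tibble::tibble(
      dataset = ds,
      n_runs = length(diffs),
      mean_difference = mean(diffs),
      wilcoxon_p = wp,
      cohens_d = d_eff,
      ci_lower = ci$lower,
      ci_upper = ci$upper,
      levene_p = lev$p_value
    )
  })
  structure(
    list(per_dataset = per_dataset,
         holm = holm_bonferroni(per_dataset$wilcoxon_p, alpha = alpha),
         alpha = alpha),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> over", nrow(x$per_dataset), "datasets;",
      sum(x$holm$rejected), "rejections at FWER", x$alpha, "\n")
  print(x$per_dataset)
  invisible(x)
}

#' Write a method comparison to JSON
#'
#' @param comparison A [compare_methods()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(
    list(per_dataset = comparison$per_dataset,
         holm = tibble::as_tibble(comparison$holm),
         alpha = comparison$alpha),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Bottom-row column average
#'
#' Arithmetic mean of per-dataset accuracies, reported to 3 decimals —
#' the convention of published comparison tables.
#'
#' @param values Nonempty numeric vector.
#' @return The mean, rounded to 3 decimals.
#' @export
#' @examples
#' aggregate_column_average(reference_accuracies()$mpa_pnn) # 91.047
aggregate_column_average <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("`values` must be a nonempty numeric vector.", call. = FALSE)
  }
  round(mean(values), 3)
}
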