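#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an optimizer run
#'
#' One row per iteration of the convergence trace.
#'
#' @param x An `mpa_result`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `best_fitness`.
#' @export
tidy.mpa_result <- function(x, ...) {
  x$trace
}

#' @export
glance.mpa_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    iterations = x$iterations_executed,
    evaluations = x$evaluations_used,
    direction = x$direction
  )
}

#' Tidy a trained MPA-PNN run
#'
#' @param x An `mpa_pnn` object.
#' @param ... Unused.
#' @return The per-iteration training-fitness trace tibble.
#' @export
tidy.mpa_pnn <- function(x, ...) {
  x$trace
}

#' @export
glance.mpa_pnn <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    baseline_fitness = x$baseline_fitness,
    improvement = x$best_fitness - x$baseline_fitness,
    evaluations = x$evaluations_used,
    seed = x$seed,
    mode = x$mode
  )
}

#' Tidy a fitted PNN
#'
#' One row per class of the summation layer.
#'
#' @param x A `pnn`.
#' @param ... Unused.
#' @return A tibble with `class`, `count`, `bias`, `cost`.
#' @export
tidy.pnn <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    count = as.integer(x$class_counts),
    bias = unname(x$class_biases),
    cost = unname(x$class_costs)
  )
}

#' @export
glance.pnn <- function(x, ...) {
  tibble::tibble(
    n_centers = nrow(x$centers),
    n_features = ncol(x$centers),
    n_classes = length(x$classes),
    sigma = x$sigma
  )
}

#' @export
tidy.holm_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(
    datasets = nrow(x$per_dataset),
    rejections = sum(x$holm$rejected),
    alpha = x$alpha,
    mean_difference = mean(x$per_dataset$mean_difference)
  )
}

#' @export
tidy.method_comparison <- function(x, ...) {
  x$per_dataset
}

#' Convergence-curve plot for an optimizer or trainer run
#'
#' @param object An `mpa_result` or `mpa_pnn`.
#' @param ... Unused.
#' @return A ggplot of best fitness versus iteration.
#' @export
autoplot.mpa_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = "MPA convergence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mpa_pnn <- function(object, ...) {
  autoplot.mpa_result(object, ...) +
    ggplot2::labs(y = "LOO training accuracy",
                  title = "MPA-PNN training convergence")
}

#' Accuracy distributions across benchmark runs
#'
#' Boxplots of per-run test accuracy per dataset and method, the usual
#' run-variability display for seeded benchmarks.
#'
#' @param object A `benchmark_report` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$dataset, y = .data$accuracy,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "Test accuracy (%)", fill = "Method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
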