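#' Brownian step matrix
#'
#' Draws a `rows` x `cols` matrix of independent standard-normal steps
#' (mean 0, variance 1), the Brownian-motion component of the Marine
#' Predators Algorithm. Draws are taken from R's global RNG stream so that
#' a whole optimizer run is reproducible from a single seed.
#'
#' @param rows,cols Positive integers giving the matrix shape.
#' @return A numeric `rows` x `cols` matrix.
#' @seealso [sample_levy()] for the heavy-tailed exploration steps.
#' @export
#' @examples
#' set.seed(1)
#' sample_brownian(3, 2)
sample_brownian <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  matrix(stats::rnorm(rows * cols), nrow = rows, ncol = cols)
}

#' Scale parameter of the Mantegna Levy-step construction
#'
#' @param beta Stability exponent in (0, 2].
#' @return The numerator sigma_u of the Mantegna construction.
#' @export
mantegna_sigma <- function(beta) {
  check_beta(beta)
  (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 2) {
    stop("`beta` must be a single number in (0, 2].", call. = FALSE)
  }
  invisible(beta)
}

#' Levy-flight step matrix
#'
#' Draws heavy-tailed steps via the Mantegna construction
#' `x = u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and
#' `sigma_u = mantegna_sigma(beta)`. At `beta = 2` the construction
#' degenerates to a Gaussian (no power-law tail); smaller `beta` gives
#' heavier tails and the occasional long exploratory jump.
#'
#' Consumes `2 * rows * cols` normal draws from the global RNG, `u` first
#' then `v`.
#'
#' @inheritParams sample_brownian
#' @param beta Stability exponent in (0, 2]; the optimizer default is 1.5.
#' @return A numeric `rows` x `cols` matrix.
#' @export
#' @examples
#' set.seed(1)
#' sample_levy(3, 2, beta = 1.5)
sample_levy <- function(rows, cols, beta = 1.5) {
  stopifnot(rows >= 1, cols >= 1)
  check_beta(beta)
  n <- rows * cols
  u <- stats::rnorm(n, sd = mantegna_sigma(beta))
  v <- stats::rnorm(n)
  matrix(u / abs(v)^(1 / beta), nrow = rows, ncol = cols)
}

#' Adaptive step-size multiplier CF
#'
#' `CF(t) = (1 - t/t_max)^(2^(t/t_max))`, the factor that shrinks predator
#' moves as the run progresses: CF(0) = 1, CF(t_max) = 0, strictly
#' decreasing in between.
#'
#' @param t Iteration index in `[0, t_max]`.
#' @param t_max Total number of iterations (positive).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' compute_cf(50, 100) # 0.5^sqrt(2)
compute_cf <- function(t, t_max) {
  stopifnot(t_max > 0)
  if (t < 0 || t > t_max) {
    stop("`t` must lie in [0, t_max].", call. = FALSE)
  }
  (1 - t / t_max)^(2^(t / t_max))
}
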