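# Exact null distribution of the signed-rank sum via generating-function
# convolution: P(W+ = s) for all achievable s, with midranks doubled so
# sums stay integral. Equivalent to enumerating all 2^n sign assignments.
signed_rank_null <- function(ranks2) {
  max_sum <- sum(ranks2)
  counts <- numeric(max_sum + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(max_sum + 1 - r)])
    counts <- counts + shifted
  }
  counts / 2^length(ranks2)
}

#' Wilcoxon signed-rank test for paired results
#'
#' Compares two equal-length result vectors (e.g. per-seed accuracies of
#' two methods). Zero differences are dropped (Wilcoxon convention);
#' absolute differences are ranked with midranks. The statistic is the
#' positive-rank sum `V`. For at most `exact_limit` nonzero differences
#' the two-sided p-value comes from the exact null distribution of `V`
#' (computed by convolution, identical to full sign enumeration); beyond
#' that, a normal approximation with continuity and tie correction is
#' used.
#'
#' @param method_a,method_b Equal-length numeric vectors.
#' @param exact_limit Largest number of nonzero differences handled
#'   exactly, default 25.
#' @return A one-row tibble: `statistic` (V), `p_value`, `n_nonzero`,
#'   `method` ("exact" or "normal_approx").
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
wilcoxon_signed_rank <- function(method_a, method_b, exact_limit = 25) {
  stopifnot(length(method_a) == length(method_b), length(method_a) >= 2)
  d <- method_a - method_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("Degenerate pairing: all differences are zero.", call. = FALSE)
  }
  r <- rank(abs(d), ties.method = "average")
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    null <- signed_rank_null(as.integer(round(2 * r)))
    v2 <- as.integer(round(2 * v))
    p_le <- sum(null[seq_len(v2 + 1)])
    p_ge <- sum(null[seq(v2 + 1, length(null))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  tibble::tibble(statistic = v, p_value = p, n_nonzero = n, method = method)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and compares rank i against the adjusted
#' threshold `alpha / (k - i + 1)`. A hypothesis is rejected only if its
#' p-value meets its threshold *and* every earlier rank was rejected: the
#' procedure stops at the first failure, so rejections always form a
#' prefix of the sorted order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level, default 0.05.
#' @return A tibble of class `holm_result`, one row per hypothesis in
#'   ascending-p order: `rank`, `original_index`, `p_value`, `threshold`,
#'   `rejected`. Attribute `stop_rank` gives the first non-rejected rank
#'   (`k + 1` if all are rejected).
#' @export
#' @examples
#' holm_bonferroni(c(0.03, 0.011))
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    stop("`p_values` must be nonempty.", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop("All p-values must lie in [0, 1].", call. = FALSE)
  }
  k <- length(p_values)
  ord <- order(p_values)
  sorted_p <- p_values[ord]
  thresholds <- alpha / (k - seq_len(k) + 1)
  pass <- sorted_p <= thresholds
  stop_rank <- if (all(pass)) k + 1L else min(which(!pass))
  rejected <- seq_len(k) < stop_rank
  out <- tibble::tibble(
    rank = seq_len(k),
    original_index = ord,
    p_value = sorted_p,
    threshold = thresholds,
    rejected = rejected
  )
  attr(out, "stop_rank") <- stop_rank
  attr(out, "alpha") <- alpha
  class(out) <- c("holm_result", class(out))
  out
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval for an arbitrary
#' statistic: the bias correction `z0` comes from the fraction of the
#' bootstrap distribution below the point estimate, the acceleration `a`
#' from the jackknife third-moment (skewness) formula, and the endpoints
#' are the correspondingly adjusted percentiles of the bootstrap
#' distribution. Constant data yields a zero-width interval at the
#' constant.
#'
#' @param data Numeric vector, length at least 3.
#' @param statistic Function of a numeric vector returning a finite
#'   number; default [mean()].
#' @param B Number of bootstrap resamples, default 10000.
#' @param level Coverage level, default 0.95.
#' @param seed RNG seed for resampling.
#' @param z0,accel Optional overrides of the bias correction and
#'   acceleration (setting both to 0 reduces BCa to the plain percentile
#'   interval; used for validation).
#' @return A one-row tibble of class `bca_ci`: `point_estimate`, `lower`,
#'   `upper`, `level`, `B`, `z0`, `accel`, `seed`.
#' @export
bca_bootstrap_ci <- function(data, statistic = mean, B = 10000, level = 0.95,
                             seed = 0, z0 = NULL, accel = NULL) {
  n <- length(data)
  stopifnot(n >= 3, B >= 2, level > 0, level < 1)
  t0 <- statistic(data)
  if (!is.finite(t0)) {
    stop("`statistic` returned a non-finite value.", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  boots <- vapply(seq_len(B), function(b) {
    statistic(data[sample.int(n, n, replace = TRUE)])
  }, numeric(1))

  if (all(boots == t0)) {
    out <- tibble::tibble(point_estimate = t0, lower = t0, upper = t0,
                          level = level, B = B, z0 = 0, accel = 0, seed = seed)
    class(out) <- c("bca_ci", class(out))
    return(out)
  }

  if (is.null(z0)) {
    frac_below <- mean(boots < t0)
    # guard the degenerate 0/1 fractions that would give infinite z0
    frac_below <- min(max(frac_below, 1 / (2 * B)), 1 - 1 / (2 * B))
    z0 <- stats::qnorm(frac_below)
  }
  if (is.null(accel)) {
    jack <- vapply(seq_len(n), function(i) statistic(data[-i]), numeric(1))
    centered <- mean(jack) - jack
    denom <- sum(centered^2)^1.5
    accel <- if (denom == 0) 0 else sum(centered^3) / (6 * denom)
  }

  z_alpha <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + z_alpha) / (1 - accel * (z0 + z_alpha)))
  endpoints <- unname(stats::quantile(boots, probs = adj, type = 6))
  out <- tibble::tibble(
    point_estimate = t0, lower = endpoints[1], upper = endpoints[2],
    level = level, B = B, z0 = z0, accel = accel, seed = seed
  )
  class(out) <- c("bca_ci", class(out))
  out
}

#' Cohen's d for paired results
#'
#' Standardized mean difference for a paired design: the mean of the
#' per-pair differences divided by their standard deviation.
#'
#' @param method_a,method_b Equal-length numeric vectors (length >= 2).
#' @return A single number; positive when `method_a` outscores
#'   `method_b`. Identical vectors give 0.
#' @export
cohens_d <- function(method_a, method_b) {
  stopifnot(length(method_a) == length(method_b), length(method_a) >= 2)
  d <- method_a - method_b
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(0)
    }
    stop("Zero spread with nonzero mean difference: effect size is infinite.",
         call. = FALSE)
  }
  mean(d) / s
}

#' Levene's test for equality of variances
#'
#' Classical (mean-centered) Levene: per-group absolute deviations from
#' the group mean feed a one-way ANOVA F statistic `W` with `(k - 1,
#' N - k)` degrees of freedom.
#'
#' @param values Numeric vector of observations, or a list of numeric
#'   group vectors (then `groups` is ignored).
#' @param groups Group labels aligned with `values`.
#' @return A one-row tibble: `statistic` (W), `p_value`, `df1`, `df2`.
#' @export
#' @examples
#' levene_test(list(rnorm(20), rnorm(20, sd = 3)))
levene_test <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) {
    stop("Levene's test needs at least 2 groups.", call. = FALSE)
  }
  if (any(sizes < 2)) {
    stop("Every group needs at least 2 observations.", call. = FALSE)
  }
  k <- length(sizes)
  n_total <- length(values)
  group_means <- tapply(values, groups, mean)
  z <- abs(values - group_means[groups])
  zbar_groups <- tapply(z, groups, mean)
  zbar <- mean(z)
  numerator <- sum(as.numeric(sizes) * (zbar_groups - zbar)^2) / (k - 1)
  denominator <- sum((z - zbar_groups[groups])^2) / (n_total - k)
  w <- if (numerator == 0) 0 else numerator / denominator
  p <- stats::pf(w, k - 1, n_total - k, lower.tail = FALSE)
  tibble::tibble(statistic = w, p_value = p, df1 = k - 1, df2 = n_total - k)
}

correlation_t_p <- function(r, n) {
  if (abs(r) >= 1) {
    return(0)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), n - 2)
}

#' Rank and linear correlation with t-approximated p-values
#'
#' Spearman's rho (Pearson on midranks) and Pearson's r for the same
#' pair of vectors, each with a two-sided p-value from the
#' t-approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, length at least 3.
#' @return A one-row tibble: `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`, `n`.
#' @export
rank_and_linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined for a constant vector.", call. = FALSE)
  }
  n <- length(x)
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  r <- stats::cor(x, y)
  tibble::tibble(
    spearman_rho = rho,
    spearman_p = correlation_t_p(rho, n),
    pearson_r = r,
    pearson_p = correlation_t_p(r, n),
    n = n
  )
}
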