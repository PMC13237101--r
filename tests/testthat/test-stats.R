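test_that("signed-rank exact p matches the all-positive worked case and symmetry", {
  a <- c(2, 4, 6, 8, 10, 12)
  b <- c(1, 2, 3, 4, 5, 6) # differences 1..6, all positive
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)
  expect_equal(res$method, "exact")
  flipped <- wilcoxon_signed_rank(b, a)
  expect_equal(flipped$p_value, res$p_value)
  expect_error(wilcoxon_signed_rank(a, a), "Degenerate")
})

test_that("exact signed-rank p equals literal 2^n enumeration on random data", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    d <- round(stats::rnorm(n), 2)
    d[d == 0] <- 0.01
    res <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(res$p_value, oracle_wilcoxon_enumeration(d),
                 tolerance = 1e-12)
  }
  # and matches stats::wilcox.test when there are no ties
  set.seed(42)
  d <- stats::rnorm(12)
  got <- wilcoxon_signed_rank(d, rep(0, 12))
  want <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-12)
  expect_equal(got$statistic, unname(want$statistic))
})

test_that("normal approximation agrees with the exact route near the cutover", {
  set.seed(43)
  d <- stats::rnorm(20)
  exact <- wilcoxon_signed_rank(d, rep(0, 20), exact_limit = 25)
  approx <- wilcoxon_signed_rank(d, rep(0, 20), exact_limit = 10)
  expect_equal(exact$method, "exact")
  expect_equal(approx$method, "normal_approx")
  expect_lt(abs(exact$p_value - approx$p_value), 0.01)
})

test_that("Holm step-down rejects a prefix and matches p.adjust", {
  res <- holm_bonferroni(c(0.03, 0.011), alpha = 0.05)
  expect_equal(res$p_value, c(0.011, 0.03))
  expect_equal(res$threshold, c(0.025, 0.05))
  expect_true(all(res$rejected))
  # rejections are a prefix and a subset of the uncorrected set
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(3:30, 1))^2
    out <- holm_bonferroni(p, alpha = 0.05)
    rej <- out$rejected
    expect_true(all(diff(as.integer(rej)) <= 0)) # prefix
    expect_true(all(out$p_value[rej] <= 0.05))
    expect_equal(out$threshold[length(p)], 0.05) # last threshold is alpha
    # strict step-down is exactly p.adjust's holm rule
    want <- stats::p.adjust(out$p_value, method = "holm") <= 0.05
    expect_equal(rej, unname(want))
  }
  expect_error(holm_bonferroni(numeric(0)), "nonempty")
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BCa collapses on constant data and reduces to percentile when forced", {
  const <- bca_bootstrap_ci(rep(2.5, 10), B = 100, seed = 1)
  expect_equal(const$lower, 2.5)
  expect_equal(const$upper, 2.5)
  expect_equal(const$point_estimate, 2.5)

  set.seed(2)
  x <- stats::rnorm(25)
  forced <- bca_bootstrap_ci(x, B = 2000, seed = 7, z0 = 0, accel = 0)
  # rebuild the same bootstrap distribution and take plain percentiles
  set.seed(7)
  boots <- replicate(2000, mean(x[sample.int(25, 25, replace = TRUE)]))
  want <- unname(stats::quantile(boots, c(0.025, 0.975), type = 6))
  expect_equal(c(forced$lower, forced$upper), want, tolerance = 1e-12)
})

test_that("BCa bias correction is near zero for a symmetric sample", {
  set.seed(3)
  half <- stats::rnorm(40)
  sym <- c(half, -half) # mirror-augmented, exactly symmetric about 0
  res <- bca_bootstrap_ci(sym, B = 4000, seed = 11)
  expect_lt(abs(res$z0), 0.05)
  expect_lte(res$lower, res$point_estimate)
  expect_gte(res$upper, res$point_estimate)
})

test_that("BCa endpoints track boot::boot.ci on a skewed sample", {
  skip_if_not_installed("boot")
  set.seed(4)
  x <- stats::rexp(40)
  got <- bca_bootstrap_ci(x, B = 6000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 6000)
  want <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # independent resampling streams: agree to within a few percent of spread
  tol <- 0.1 * stats::sd(x)
  expect_lt(abs(got$lower - want[1]), tol)
  expect_lt(abs(got$upper - want[2]), tol)
})

test_that("Cohen's d follows its definition and sign convention", {
  expect_equal(cohens_d(1:10, 1:10), 0)
  # differences with mean equal to their sd -> exactly 1
  b <- c(0, 0, 0, 0)
  a <- c(1, 2, 3, 4) - mean(1:4) + stats::sd(1:4)
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)
  expect_equal(cohens_d(b, a), -1, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(0, 0)), "infinite")
})

test_that("Levene W is zero for identical groups and matches car on random data", {
  g <- stats::rnorm(20)
  res <- levene_test(list(g, g))
  expect_equal(res$statistic, 0)
  # power: one group scaled by 3 is detected
  set.seed(6)
  big <- levene_test(list(stats::rnorm(200), 3 * stats::rnorm(200)))
  expect_lt(big$p_value, 0.01)
  skip_if_not_installed("car")
  set.seed(7)
  values <- c(stats::rnorm(30), stats::rnorm(25, sd = 1.8))
  groups <- rep(c("a", "b"), c(30, 25))
  got <- levene_test(values, groups)
  want <- car::leveneTest(values ~ factor(groups), center = mean)
  expect_equal(got$statistic, want$`F value`[1], tolerance = 1e-9)
  expect_equal(got$p_value, want$`Pr(>F)`[1], tolerance = 1e-9)
  expect_error(levene_test(list(1, c(1, 2))), "at least 2")
})

test_that("Levene type-I error is calibrated at the nominal level", {
  set.seed(8)
  rejections <- vapply(1:2000, function(i) {
    levene_test(list(stats::rnorm(30), stats::rnorm(30)))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("Spearman equals Pearson on ranks, with t-approximated p-values", {
  set.seed(9)
  x <- stats::rnorm(15)
  y <- x^3 + 0.1 * stats::rnorm(15)
  res <- rank_and_linear_correlation(x, y)
  expect_equal(res$spearman_rho, stats::cor(rank(x), rank(y)),
               tolerance = 1e-12)
  # perfectly monotone pair
  mono <- rank_and_linear_correlation(1:10, exp(1:10))
  expect_equal(mono$spearman_rho, 1)
  expect_equal(mono$spearman_p, 0)
  # Pearson p matches cor.test's t-approximation
  ct <- stats::cor.test(x, y)
  expect_equal(res$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$pearson_p, ct$p.value, tolerance = 1e-12)
  expect_error(rank_and_linear_correlation(rep(1, 5), 1:5), "constant")
})
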