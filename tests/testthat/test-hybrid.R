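far_toy <- function() {
  tibble::tibble(
    f1 = c(0.0, 0.1, 0.9, 1.0),
    f2 = c(0.0, 0.1, 0.9, 1.0),
    label = c("A", "A", "B", "B")
  )
}

test_that("encoding dimensions follow the mode formulas", {
  expect_equal(encoding_dimension("pattern_bias", 10, 2, 8), 12L)
  expect_equal(encoding_dimension("centers", 10, 2, 3), 32L)
  # a 518-row binary training split in pattern_bias mode
  expect_equal(encoding_dimension("pattern_bias", 518, 2, 8), 520L)
  expect_error(encoding_dimension("other", 10, 2, 8))
})

test_that("decode installs parameters and validates its input", {
  base <- pnn(far_toy(), sigma = 0.1)
  theta <- c(0.5, 0.6, 0.7, 0.8, 0.1, 0.2)
  model <- decode_theta(theta, "pattern_bias", base)
  expect_equal(model$pattern_weights, theta[1:4])
  expect_equal(unname(model$class_biases), theta[5:6])
  expect_equal(model$centers, base$centers)
  expect_error(decode_theta(theta[1:5], "pattern_bias", base), "length")
  expect_error(decode_theta(c(theta[1:5], 1.5), "pattern_bias", base),
               "\\[0, 1\\]")
  # centers mode reshapes row-major and keeps alpha at 1
  theta_c <- c(seq(0, 1, length.out = 8), 0, 0)
  mc <- decode_theta(theta_c, "centers", base)
  expect_equal(unname(mc$centers[1, ]), theta_c[1:2])
  expect_equal(unname(mc$centers[4, ]), theta_c[7:8])
  expect_equal(mc$pattern_weights, rep(1, 4))
})

test_that("the identity encoding reproduces the vanilla PNN in both modes", {
  train <- toy_blobs(n = 50, seed = 7, separation = 2, noise = 0.1)
  base <- pnn(train)
  probe <- matrix(stats::runif(40), ncol = 2)
  want <- predict(base, probe)$.pred_class
  for (mode in c("pattern_bias", "centers")) {
    theta <- identity_theta(mode, base)
    expect_equal(length(theta),
                 encoding_dimension(mode, 50, 2, 2))
    model <- decode_theta(theta, mode, base)
    expect_equal(predict(model, probe)$.pred_class, want)
  }
})

test_that("LOO fitness matches hand-evaluated toy cases and stays in [0,1]", {
  base <- pnn(far_toy(), sigma = 0.1)
  id <- identity_theta("pattern_bias", base)
  # each point's nearest non-self centre shares its class -> fitness 1
  expect_equal(pnn_fitness(id, "pattern_bias", far_toy(), base), 1)
  # relocate one A-point next to the B blob: it and its nearest neighbour
  # both misclassify in LOO, the remaining two stay correct -> 0.5
  # (hand check: A2 = (0.85, 0.85) sits 0.0707 from B1 = (0.9, 0.9), so A2
  # scores f_B = e^{-0.25}/2 > f_A and B1 scores f_A = e^{-0.25}/2 > f_B =
  # e^{-1}/2; A1 keeps A2 as nearest kernel and B2 keeps B1.)
  moved <- far_toy()
  moved$f1[2] <- 0.85
  moved$f2[2] <- 0.85
  base2 <- pnn(moved, sigma = 0.1)
  expect_equal(pnn_fitness(identity_theta("pattern_bias", base2),
                           "pattern_bias", moved, base2), 0.5)
  set.seed(1)
  for (i in 1:5) {
    theta <- stats::runif(length(id))
    f <- pnn_fitness(theta, "pattern_bias", far_toy(), base)
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("the cached fitness path agrees with the generic decode-and-predict path", {
  train <- toy_blobs(n = 40, seed = 11, separation = 2, noise = 0.1)
  base <- pnn(train)
  ctx <- mpapnn:::make_fitness_context(base, train$label)
  set.seed(2)
  for (i in 1:10) {
    theta <- stats::runif(42)
    expect_equal(mpapnn:::fitness_from_context(theta, ctx, 2),
                 pnn_fitness(theta, "pattern_bias", train, base))
  }
})

test_that("MPA training never falls below the identity baseline", {
  cfg <- mpa_config(max_iterations = 5, seed = 1)
  for (s in 1:20) {
    train <- synth_dataset(dataset_spec("p", n = 40, d = 3,
                                        separation = stats::runif(1, 1, 4),
                                        noise_rate = 0.1, seed = s))
    cfg$seed <- s
    fit <- train_mpa_pnn(train, config = cfg)
    expect_gte(fit$best_fitness, fit$baseline_fitness)
    expect_true(all(diff(fit$trace$best_fitness) >= 0))
  }
})

test_that("training is deterministic and budget-accounted", {
  train <- toy_blobs(n = 60, seed = 4, separation = 2.5, noise = 0.05)
  cfg <- mpa_config(max_iterations = 10, seed = 3)
  a <- train_mpa_pnn(train, config = cfg)
  b <- train_mpa_pnn(train, config = cfg)
  expect_identical(a$best_theta, b$best_theta)
  expect_identical(a$trace, b$trace)
  expect_equal(nrow(a$trace), 10)
  expect_equal(a$evaluations_used, 10 * (1 + 2 * 10))
  # patience can shorten the trace but never lengthens it
  cfg_pat <- mpa_config(max_iterations = 100, patience = 5, seed = 3)
  fit <- train_mpa_pnn(train, config = cfg_pat)
  expect_lte(nrow(fit$trace), 100)
})

test_that("random search is reproducible with a non-decreasing best-so-far", {
  train <- toy_blobs(n = 40, seed = 8, separation = 2, noise = 0.1)
  a <- train_random_search(train, budget = 30, seed = 5)
  b <- train_random_search(train, budget = 30, seed = 5)
  expect_identical(a$best_theta, b$best_theta)
  expect_true(all(diff(a$trace$best_fitness) >= 0))
  expect_equal(a$evaluations_used, 30)
  # budget 1: the result is the fitness of the single drawn point
  one <- train_random_search(train, budget = 1, seed = 5)
  base <- pnn(train)
  expect_equal(one$best_fitness,
               pnn_fitness(one$best_theta, "pattern_bias", train, base))
  # a longer run with the same seed extends the same draw stream
  longer <- train_random_search(train, budget = 60, seed = 5)
  expect_equal(longer$trace$best_fitness[1:30], a$trace$best_fitness)
})
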