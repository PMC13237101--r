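test_that("search space rejects degenerate or inconsistent bounds", {
  expect_error(search_space(2, 2), "strictly below")
  expect_error(search_space(c(0, 0), c(1, -1)), "strictly below")
  expect_error(search_space(0, c(1, 2)), "equal positive length")
  sp <- search_space(rep(0, 5), rep(1, 5))
  expect_equal(sp$dim, 5)
})

test_that("CF is exact at its closed-form values and strictly decreasing", {
  expect_equal(compute_cf(0, 100), 1)
  expect_equal(compute_cf(100, 100), 0)
  expect_equal(compute_cf(50, 100), 0.5^sqrt(2), tolerance = 1e-12)
  grid <- vapply(0:100, compute_cf, numeric(1), t_max = 100)
  expect_true(all(diff(grid) < 0))
  expect_error(compute_cf(101, 100), "lie in")
})

test_that("Brownian sampler has standard-normal moments and independent columns", {
  set.seed(7)
  x <- sample_brownian(5e4, 2)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(stats::var(as.vector(x)) - 1), 0.03)
  expect_lt(abs(stats::cor(x[, 1], x[, 2])), 0.02)
})

test_that("Mantegna sigma matches its closed form and beta is validated", {
  # direct evaluation with Gamma(2.5) and Gamma(1.25)
  expected <- (gamma(2.5) * sin(0.75 * pi) / (gamma(1.25) * 1.5 * 2^0.25))^(1 / 1.5)
  expect_equal(mantegna_sigma(1.5), expected, tolerance = 1e-12)
  expect_equal(mantegna_sigma(1.5), 0.6966, tolerance = 1e-4)
  expect_error(sample_levy(2, 2, beta = 0), "\\(0, 2\\]")
  expect_error(sample_levy(2, 2, beta = 2.5), "\\(0, 2\\]")
})

test_that("Levy tails are Gaussian at beta = 2 and heavier than Gaussian at beta = 1.5", {
  set.seed(11)
  g2 <- sample_levy(1e6, 1, beta = 2)
  expect_lt(mean(abs(g2) > 6), 1e-4)
  set.seed(12)
  levy <- sample_levy(1e6, 1, beta = 1.5)
  gauss <- sample_brownian(1e6, 1)
  expect_gt(mean(abs(levy) > 10), mean(abs(gauss) > 10))
  expect_gt(mean(abs(levy) > 10), 0)
})

test_that("population initialization respects bounds and is seed-deterministic", {
  sp <- search_space(rep(0, 5), rep(1, 5))
  cfg <- mpa_config(population_size = 10, seed = 3)
  obj <- function(x) sum(x)
  set.seed(cfg$seed)
  a <- mpapnn:::initialize_population(sp, cfg, obj)
  set.seed(cfg$seed)
  b <- mpapnn:::initialize_population(sp, cfg, obj)
  expect_true(all(a$positions >= 0 & a$positions <= 1))
  expect_identical(a$positions, b$positions)
  expect_equal(a$elite$fitness, min(a$fitness))
  expect_equal(a$elite$memory_fitness, a$fitness)
  expect_error(
    {
      set.seed(1)
      mpapnn:::initialize_population(sp, cfg, function(x) NaN)
    },
    "non-finite"
  )
})

test_that("prey and predator move rules match hand-evaluated algebra", {
  # dim 1, elite 0.8, U 0.2, noise 0.5, R 1, P 0.5:
  # S = 0.5 * (0.8 - 0.5 * 0.2) = 0.35; U' = 0.2 + 0.5 * 1 * 0.35 = 0.375
  u <- matrix(0.2, 1, 1)
  out <- mpapnn:::prey_move(u, 0.8, matrix(0.5), matrix(1), 0.5)
  expect_equal(out[1, 1], 0.375)
  # predator rule at CF = 1: S = 0.5 * (0.5 * 0.8 - 0.2) = 0.1;
  # U' = 0.8 + 0.5 * 1 * 0.1 = 0.85
  out <- mpapnn:::predator_move(u, 0.8, matrix(0.5), 0.5, 1)
  expect_equal(out[1, 1], 0.85)
  # zero noise in the prey rule leaves positions unchanged
  out <- mpapnn:::prey_move(u, 0.8, matrix(0), matrix(1), 0.5)
  expect_equal(out[1, 1], 0.2)
})

test_that("the iteration schedule partitions [0, t_max) into the three phases", {
  t_max <- 100
  phases <- vapply(0:99, mpapnn:::phase_of, integer(1), t_max = t_max)
  expect_equal(unique(phases[1:33]), 1L)   # t = 10 -> phase 1
  expect_equal(unique(phases[35:66]), 2L)  # t = 50 -> phase 2
  expect_equal(unique(phases[68:100]), 3L) # t = 90 -> phase 3
  expect_true(all(phases %in% 1:3))
  # every t maps to exactly one phase (vapply guarantees a single value)
  expect_length(phases, 100)
})

test_that("phase updates stay inside the box in every phase", {
  sp <- search_space(rep(-1, 4), rep(1, 4))
  cfg <- mpa_config(population_size = 9, max_iterations = 90, seed = 5)
  set.seed(5)
  pos <- matrix(stats::runif(36, -1, 1), 9, 4)
  elite <- pos[1, ]
  for (t in c(10, 45, 80)) {
    out <- phase_update(pos, elite, t, cfg, sp)
    expect_true(all(out >= -1 & out <= 1))
    expect_equal(dim(out), dim(pos))
  }
  expect_error(phase_update(pos[, 1:2], elite, 10, cfg, sp), "dimensions")
})

test_that("FADs perturbation respects its degenerate cases and bounds", {
  sp <- search_space(rep(0, 3), rep(1, 3))
  # fads = 0: only the differential branch runs; identical rows cannot move
  cfg0 <- mpa_config(population_size = 4, max_iterations = 10,
                     fads_probability = 0, seed = 1)
  pos <- matrix(0.5, 4, 3)
  set.seed(1)
  expect_equal(fads_perturbation(pos, pos[1, ], 5, cfg0, sp), pos)
  # t = t_max (CF = 0) with the masked branch forced: positions unchanged
  cfg1 <- mpa_config(population_size = 4, max_iterations = 10,
                     fads_probability = 1, seed = 1)
  set.seed(1)
  expect_equal(fads_perturbation(pos, pos[1, ], 10, cfg1, sp), pos)
  # arbitrary inputs stay clamped, under both mask conventions
  for (conv in c("sparse", "paper_literal")) {
    cfg <- mpa_config(population_size = 6, max_iterations = 10,
                      fads_w_convention = conv, seed = 2)
    set.seed(2)
    rand_pos <- matrix(stats::runif(18), 6, 3)
    out <- fads_perturbation(rand_pos, rand_pos[1, ], 2, cfg, sp)
    expect_true(all(out >= 0 & out <= 1))
  }
  # single-individual populations fall back to the masked branch
  cfgN1 <- mpa_config(population_size = 1, max_iterations = 10,
                      fads_probability = 0, seed = 3)
  set.seed(3)
  out <- fads_perturbation(matrix(0.5, 1, 3), rep(0.5, 3), 2, cfgN1, sp)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("a constant objective yields a flat trace at the constant", {
  sp <- search_space(rep(0, 3), rep(1, 3))
  res <- mpa_optimize(function(x) 3, sp,
                      mpa_config(max_iterations = 10, seed = 1))
  expect_equal(res$best_fitness, 3)
  expect_true(all(res$trace$best_fitness == 3))
  expect_equal(res$iterations_executed, 10)
})

test_that("elite traces are monotone and runs are seed-deterministic", {
  sp <- search_space(rep(-5, 4), rep(5, 4))
  rosenbrock <- function(x) sum(100 * (x[-1] - x[-4]^2)^2 + (1 - x[-4])^2)
  for (s in 1:3) {
    res <- mpa_optimize(rosenbrock, sp,
                        mpa_config(max_iterations = 40, seed = s))
    expect_true(all(diff(res$trace$best_fitness) <= 0))
    expect_true(all(res$best_position >= -5 & res$best_position <= 5))
  }
  a <- mpa_optimize(rosenbrock, sp, mpa_config(max_iterations = 30, seed = 9))
  b <- mpa_optimize(rosenbrock, sp, mpa_config(max_iterations = 30, seed = 9))
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
  # maximization flips the trace direction
  res <- mpa_optimize(function(x) -sum(x^2), sp,
                      mpa_config(max_iterations = 30, seed = 2),
                      direction = "maximize")
  expect_true(all(diff(res$trace$best_fitness) >= 0))
})

test_that("patience stops a stalled run early and budgets are accounted", {
  sp <- search_space(rep(0, 2), rep(1, 2))
  cfg <- mpa_config(population_size = 5, max_iterations = 50, patience = 3,
                    seed = 1)
  res <- mpa_optimize(function(x) 1, sp, cfg)
  expect_equal(res$iterations_executed, 3)
  cfg_full <- mpa_config(population_size = 5, max_iterations = 20, seed = 1)
  res <- mpa_optimize(function(x) sum(x), sp, cfg_full)
  expect_equal(res$evaluations_used, 5 * (1 + 2 * 20))
})

test_that("trace CSV export round-trips", {
  sp <- search_space(rep(0, 2), rep(1, 2))
  res <- mpa_optimize(function(x) sum(x), sp,
                      mpa_config(max_iterations = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$best_fitness, res$trace$best_fitness)
})
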