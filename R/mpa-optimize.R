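#' Bounded continuous search space
#'
#' The box the Marine Predators Algorithm searches over. Bounds must be
#' strictly ordered componentwise; degenerate dimensions are rejected.
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `lower[j] < upper[j]` for every `j`.
#' @return An object of class `search_space` with fields `lower`, `upper`,
#'   `dim`.
#' @export
#' @examples
#' search_space(rep(0, 5), rep(1, 5))
search_space <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != length(upper) || length(lower) < 1L) {
    stop("`lower` and `upper` must be numeric vectors of equal positive length.",
         call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("Search-space bounds must be finite.", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("Every lower bound must be strictly below its upper bound.",
         call. = FALSE)
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         dim = length(lower)),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat("<search_space> dim =", x$dim, "\n")
  invisible(x)
}

#' Marine Predators Algorithm configuration
#'
#' Defaults reproduce the settings used throughout the MPA-PNN benchmark
#' protocol: population of 10, 100 iterations, step constant P = 0.5,
#' FADs probability 0.2, Levy exponent 1.5, elite memory always on.
#'
#' @param population_size Number of prey (search agents), default 10.
#' @param max_iterations Iteration budget `t_max`, default 100.
#' @param step_constant The scalar P multiplying every step, default 0.5.
#' @param fads_probability Probability of the FADs jump branch, in `[0, 1]`,
#'   default 0.2.
#' @param levy_exponent Stability exponent of the Levy sampler in (0, 2],
#'   default 1.5.
#' @param fads_w_convention Binary-mask convention for the FADs jump:
#'   `"sparse"` (mask entries are 1 with probability `fads_probability`,
#'   the original-algorithm reading, default) or `"paper_literal"` (the
#'   inverse: 1 with probability `1 - fads_probability`).
#' @param patience Optional early-stopping window: stop when the elite has
#'   not improved for this many consecutive iterations. `NULL` (default)
#'   disables early stopping so runs always use the full budget.
#' @param seed Non-negative integer seed for the run's RNG stream.
#' @return An object of class `mpa_config`.
#' @export
mpa_config <- function(population_size = 10,
                       max_iterations = 100,
                       step_constant = 0.5,
                       fads_probability = 0.2,
                       levy_exponent = 1.5,
                       fads_w_convention = c("sparse", "paper_literal"),
                       patience = NULL,
                       seed = 0) {
  fads_w_convention <- match.arg(fads_w_convention)
  stopifnot(
    population_size >= 1, max_iterations >= 1,
    is.numeric(step_constant), length(step_constant) == 1L,
    fads_probability >= 0, fads_probability <= 1,
    is.null(patience) || patience >= 1,
    seed >= 0
  )
  check_beta(levy_exponent)
  structure(
    list(
      population_size = as.integer(population_size),
      max_iterations = as.integer(max_iterations),
      step_constant = step_constant,
      fads_probability = fads_probability,
      levy_exponent = levy_exponent,
      fads_w_convention = fads_w_convention,
      patience = if (is.null(patience)) NULL else as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "mpa_config"
  )
}

clamp_to_bounds <- function(positions, space) {
  lo <- matrix(space$lower, nrow = nrow(positions), ncol = space$dim, byrow = TRUE)
  hi <- matrix(space$upper, nrow = nrow(positions), ncol = space$dim, byrow = TRUE)
  pmin(pmax(positions, lo), hi)
}

evaluate_population <- function(objective, positions) {
  fitness <- vapply(seq_len(nrow(positions)), function(i) {
    value <- objective(positions[i, ])
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      stop("Objective returned a non-finite value for individual ", i, ".",
           call. = FALSE)
    }
    value
  }, numeric(1))
  fitness
}

#' Initialize an MPA population
#'
#' Each coordinate is drawn as `lower + u * (upper - lower)` with `u`
#' uniform on `[0, 1]`. Fitness is evaluated for every individual; the
#' elite is the best individual and the per-index marine memory starts at
#' the initial population. Optionally, rows of `initial_solutions`
#' overwrite the first individuals (used by the hybrid trainer to seed the
#' identity encoding).
#'
#' @param space A [search_space()].
#' @param config An [mpa_config()].
#' @param objective Function of a `dim`-vector returning a finite number.
#' @param direction `"minimize"` or `"maximize"`.
#' @param initial_solutions Optional matrix (rows within bounds) seeding
#'   the first individuals.
#' @return A list with `positions`, `fitness`, and an `elite` list
#'   (`position`, `fitness`, `memory_positions`, `memory_fitness`).
#' @keywords internal
initialize_population <- function(space, config, objective,
                                  direction = "minimize",
                                  initial_solutions = NULL) {
  n <- config$population_size
  u <- matrix(stats::runif(n * space$dim), nrow = n)
  positions <- matrix(space$lower, n, space$dim, byrow = TRUE) +
    u * matrix(space$upper - space$lower, n, space$dim, byrow = TRUE)
  if (!is.null(initial_solutions)) {
    initial_solutions <- rbind(initial_solutions)
    k <- min(nrow(initial_solutions), n)
    positions[seq_len(k), ] <- initial_solutions[seq_len(k), , drop = FALSE]
    positions <- clamp_to_bounds(positions, space)
  }
  fitness <- evaluate_population(objective, positions)
  better <- if (direction == "maximize") which.max(fitness) else which.min(fitness)
  list(
    positions = positions,
    fitness = fitness,
    elite = list(
      position = positions[better, ],
      fitness = fitness[better],
      memory_positions = positions,
      memory_fitness = fitness
    )
  )
}

phase_of <- function(t, t_max) {
  if (t < t_max / 3) 1L else if (t < 2 * t_max / 3) 2L else 3L
}

#' One MPA phase update
#'
#' Applies the movement rule of the current phase to the whole population
#' and clamps to bounds:
#' * phase 1 (`t < t_max/3`, exploration): Brownian prey steps
#'   `S = R_B * (Elite - R_B * U)`, `U <- U + P * R * S`;
#' * phase 2 (middle third): the first half of indices takes Levy prey
#'   steps (`S = R_L * (Elite - R_L * U)`, `U <- U + P * R * S`), the
#'   second half takes Brownian predator steps
#'   (`S = R_B * (R_B * Elite - U)`, `U <- Elite + P * CF * S`);
#' * phase 3 (final third, exploitation): Levy predator steps
#'   `S = R_L * (R_L * Elite - U)`, `U <- Elite + P * CF * S`.
#'
#' RNG order per call: phase 1 draws `R_B` then `R`; phase 2 draws `R_L`
#' then `R` for the prey half, then `R_B` for the predator half; phase 3
#' draws `R_L`.
#'
#' @param positions N x dim population matrix.
#' @param elite_position Elite (top-predator) vector, replicated per row.
#' @param t Current iteration index (0-based).
#' @param config An [mpa_config()].
#' @param space A [search_space()].
#' @return Updated N x dim matrix, clamped to bounds.
#' @export
phase_update <- function(positions, elite_position, t, config, space) {
  if (ncol(positions) != space$dim || length(elite_position) != space$dim) {
    stop("Population/elite dimensions do not match the search space.",
         call. = FALSE)
  }
  n <- nrow(positions)
  d <- space$dim
  t_max <- config$max_iterations
  phase <- phase_of(t, t_max)
  cf <- compute_cf(t, t_max)

  if (phase == 1L) {
    rb <- sample_brownian(n, d)
    r <- matrix(stats::runif(n * d), n, d)
    out <- prey_move(positions, elite_position, rb, r, config$step_constant)
  } else if (phase == 2L) {
    n_prey <- ceiling(n / 2)
    prey <- seq_len(n_prey)
    pred <- setdiff(seq_len(n), prey)
    out <- positions
    rl <- sample_levy(n_prey, d, config$levy_exponent)
    r <- matrix(stats::runif(n_prey * d), n_prey, d)
    out[prey, ] <- prey_move(positions[prey, , drop = FALSE], elite_position,
                             rl, r, config$step_constant)
    if (length(pred) > 0) {
      rb <- sample_brownian(length(pred), d)
      out[pred, ] <- predator_move(positions[pred, , drop = FALSE],
                                   elite_position, rb, config$step_constant, cf)
    }
  } else {
    rl <- sample_levy(n, d, config$levy_exponent)
    out <- predator_move(positions, elite_position, rl, config$step_constant, cf)
  }
  clamp_to_bounds(out, space)
}

# Prey rule: S = noise * (Elite - noise * U), U' = U + P * R * S.
prey_move <- function(positions, elite_position, noise, r, p_const) {
  elite <- matrix(elite_position, nrow(positions), ncol(positions), byrow = TRUE)
  step <- noise * (elite - noise * positions)
  positions + p_const * r * step
}

# Predator rule: S = noise * (noise * Elite - U), U' = Elite + P * CF * S.
predator_move <- function(positions, elite_position, noise, p_const, cf) {
  elite <- matrix(elite_position, nrow(positions), ncol(positions), byrow = TRUE)
  step <- noise * (noise * elite - positions)
  elite + p_const * cf * step
}

#' FADs / eddy stagnation perturbation
#'
#' Per individual, a uniform draw `r5` selects one of two jumps. With
#' probability `fads_probability`: a masked long jump
#' `U <- U + CF * (lower + R * (upper - lower)) * W`, `W` a binary mask per
#' the configured convention. Otherwise a differential jump
#' `U <- U + (FADs * (1 - r) + r) * (U_r1 - U_r2)` towards the difference
#' of two distinct random individuals. Populations of size 1 always use
#' the masked branch (no pair to difference). Results are clamped.
#'
#' RNG order: the vector `r5` (length N) first, then per individual in
#' index order the branch-specific draws (masked branch: `R` length d,
#' then the mask; differential branch: scalar `r`, then the index pair).
#'
#' @inheritParams phase_update
#' @return Updated N x dim matrix, clamped to bounds.
#' @export
fads_perturbation <- function(positions, elite_position, t, config, space) {
  n <- nrow(positions)
  d <- space$dim
  cf <- compute_cf(t, config$max_iterations)
  fads <- config$fads_probability
  r5 <- stats::runif(n)
  out <- positions
  for (i in seq_len(n)) {
    if (r5[i] < fads || n < 2) {
      r <- stats::runif(d)
      mask_draw <- stats::runif(d)
      w <- if (config$fads_w_convention == "sparse") {
        as.numeric(mask_draw < fads)
      } else {
        as.numeric(mask_draw >= fads)
      }
      out[i, ] <- positions[i, ] +
        cf * (space$lower + r * (space$upper - space$lower)) * w
    } else {
      r <- stats::runif(1)
      pair <- sample.int(n, 2)
      out[i, ] <- positions[i, ] +
        (fads * (1 - r) + r) * (positions[pair[1], ] - positions[pair[2], ])
    }
  }
  clamp_to_bounds(out, space)
}

update_memory <- function(elite, positions, fitness, direction) {
  improved <- if (direction == "maximize") {
    fitness > elite$memory_fitness
  } else {
    fitness < elite$memory_fitness
  }
  elite$memory_positions[improved, ] <- positions[improved, , drop = FALSE]
  elite$memory_fitness[improved] <- fitness[improved]
  best <- if (direction == "maximize") {
    which.max(elite$memory_fitness)
  } else {
    which.min(elite$memory_fitness)
  }
  elite$position <- elite$memory_positions[best, ]
  elite$fitness <- elite$memory_fitness[best]
  elite
}

#' Run the Marine Predators Algorithm
#'
#' Full optimizer loop: initialize, then per iteration a phase update,
#' evaluation, marine-memory saving and elite update, followed by the FADs
#' perturbation with a second evaluation/memory/elite pass. Candidate
#' positions revert to the remembered per-index best whenever the new
#' fitness is worse (marine memory), so the elite trace never worsens.
#'
#' One RNG stream per run, seeded from `config$seed`; identical inputs
#' give identical traces.
#'
#' @param objective Function of a `dim`-vector returning a finite number.
#' @param space A [search_space()].
#' @param config An [mpa_config()].
#' @param direction `"minimize"` (default) or `"maximize"`.
#' @param initial_solutions Optional matrix of rows seeded into the
#'   initial population (see [initialize_population()]).
#' @return An object of class `mpa_result`: a list with `best_position`,
#'   `best_fitness`, `trace` (tibble with `iteration`, `best_fitness`),
#'   `iterations_executed`, `evaluations_used`, `direction`, `config`.
#' @export
#' @examples
#' sp <- search_space(rep(-10, 2), rep(10, 2))
#' res <- mpa_optimize(function(x) sum(x^2), sp,
#'                     mpa_config(max_iterations = 20, seed = 1))
#' res$best_fitness
mpa_optimize <- function(objective, space, config = mpa_config(),
                         direction = c("minimize", "maximize"),
                         initial_solutions = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(space, "search_space"), inherits(config, "mpa_config"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  state <- initialize_population(space, config, objective, direction,
                                 initial_solutions)
  positions <- state$positions
  elite <- state$elite
  evaluations <- config$population_size

  trace <- numeric(config$max_iterations)
  stall <- 0L
  iterations <- 0L
  for (t in seq_len(config$max_iterations) - 1L) {
    previous_best <- elite$fitness

    positions <- phase_update(positions, elite$position, t, config, space)
    fitness <- evaluate_population(objective, positions)
    evaluations <- evaluations + config$population_size
    elite <- update_memory(elite, positions, fitness, direction)
    positions <- elite$memory_positions

    positions <- fads_perturbation(positions, elite$position, t, config, space)
    fitness <- evaluate_population(objective, positions)
    evaluations <- evaluations + config$population_size
    elite <- update_memory(elite, positions, fitness, direction)
    positions <- elite$memory_positions

    iterations <- iterations + 1L
    trace[iterations] <- elite$fitness

    if (!is.null(config$patience)) {
      improved <- if (direction == "maximize") {
        elite$fitness > previous_best
      } else {
        elite$fitness < previous_best
      }
      stall <- if (improved) 0L else stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(
    list(
      best_position = elite$position,
      best_fitness = elite$fitness,
      trace = tibble::tibble(
        iteration = seq_len(iterations),
        best_fitness = trace[seq_len(iterations)]
      ),
      iterations_executed = iterations,
      evaluations_used = evaluations,
      direction = direction,
      config = config
    ),
    class = "mpa_result"
  )
}

#' @export
print.mpa_result <- function(x, ...) {
  cat("<mpa_result> ", x$direction, "d fitness ",
      format(x$best_fitness, digits = 6),
      " after ", x$iterations_executed, " iterations (",
      x$evaluations_used, " evaluations)\n", sep = "")
  invisible(x)
}

#' Write a convergence trace to CSV
#'
#' @param result An `mpa_result` or `mpa_pnn` object.
#' @param path Output CSV path (columns `iteration`, `best_fitness`).
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  readr::write_csv(result$trace, path)
  invisible(path)
}
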