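# Whale optimization algorithm (WOA): a population metaheuristic for
# box-constrained continuous minimization, modelled on the bubble-net hunting
# manoeuvre of humpback whales.  Each candidate solution ("search agent") is
# pulled toward the best solution found so far either by shrinking encirclement
# or by a logarithmic spiral, or pushed toward a random agent for exploration.

#' Linear decay schedule for the WOA coefficient a
#'
#' The control coefficient `a` descends linearly from 2 at the first iteration
#' to 0 at the last; it scales the random coefficient vector `A` and thereby
#' switches the swarm from exploration (|A| large) to exploitation (|A| small).
#'
#' @param t Iteration index, `0 <= t <= t_max`.
#' @param t_max Total number of iterations (>= 1).
#' @return The scalar `a = 2 * (1 - t / t_max)`.
#' @examples
#' woa_decay(0, 100)   # 2
#' woa_decay(50, 100)  # 1
#' woa_decay(100, 100) # 0
#' @export
woa_decay <- function(t, t_max) {
  if (!is_number(t_max) || t_max < 1) {
    stop_invalid("t_max must be a positive number, got %s", format(t_max))
  }
  if (!is_number(t) || t < 0 || t > t_max) {
    stop_invalid("iteration t must lie in [0, t_max]")
  }
  2 * (1 - t / t_max)
}

#' Draw the WOA coefficient vectors A and C
#'
#' `A = 2 a r - a` and `C = 2 r'` with `r`, `r'` independent Uniform(0, 1)
#' draws per component; components of `A` lie in `[-a, a]`, components of `C`
#' in `[0, 2]`.  Uses the current R random number stream.
#'
#' @param a Current decay coefficient in `[0, 2]`.
#' @param dim Problem dimension.
#' @return A list with numeric vectors `A` and `C` of length `dim`.
#' @export
woa_coefficients <- function(a, dim) {
  if (!is_number(a) || a < 0 || a > 2) stop_invalid("a must lie in [0, 2]")
  r <- runif(dim)
  r2 <- runif(dim)
  list(A = 2 * a * r - a, C = 2 * r2)
}

check_same_length <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L) {
    stop_invalid("position vectors must have equal length (got %s)",
                 paste(lens, collapse = ", "))
  }
}

#' Encircling position update
#'
#' Moves an agent toward the best solution: `D' = |C * x_best - x|`,
#' `x_new = x_best - A * D'` (all operations elementwise).
#'
#' @param x Current position.
#' @param x_best Best position found so far.
#' @param A,C Coefficient vectors from [woa_coefficients()].
#' @return The updated position vector.
#' @export
woa_encircle <- function(x, x_best, A, C) {
  check_same_length(x, x_best, A, C)
  d <- abs(C * x_best - x)
  x_best - A * d
}

#' Spiral (bubble-net) position update
#'
#' Moves an agent along a logarithmic spiral around the best solution:
#' `D' = |x_best - x|`, `x_new = D' * exp(b l) * cos(2 pi l) + x_best`, with
#' `l` a random constant in `[-1, 1]` drawn by the caller.
#'
#' @param x Current position.
#' @param x_best Best position found so far.
#' @param b Spiral shape constant (> 0).
#' @param l Spiral parameter in `[-1, 1]`.
#' @return The updated position vector.
#' @export
woa_spiral <- function(x, x_best, b, l) {
  check_same_length(x, x_best)
  if (!is_number(b) || b <= 0) stop_invalid("spiral constant b must be > 0")
  if (!is_number(l) || l < -1 || l > 1) stop_invalid("l must lie in [-1, 1]")
  d <- abs(x_best - x)
  d * exp(b * l) * cos(2 * pi * l) + x_best
}

#' Exploration position update
#'
#' Same form as [woa_encircle()] but relative to a randomly chosen agent
#' rather than the best one; applied when `|A| >= 1` to keep the swarm
#' searching globally.
#'
#' @param x Current position.
#' @param x_rand Position of a randomly selected agent.
#' @param A,C Coefficient vectors from [woa_coefficients()].
#' @return The updated position vector.
#' @export
woa_explore <- function(x, x_rand, A, C) {
  check_same_length(x, x_rand, A, C)
  d <- abs(C * x_rand - x)
  x_rand - A * d
}

# Initialize the optimizer state: uniform positions inside the box, all
# fitnesses evaluated, elitist best recorded (ties keep the first agent).
woa_init <- function(objective, lower, upper, pop_size, max_iter, spiral_b) {
  d <- length(lower)
  pos <- matrix(runif(pop_size * d), pop_size, d)
  pos <- sweep(pos, 2, upper - lower, `*`)
  pos <- sweep(pos, 2, lower, `+`)
  fit <- vapply(seq_len(pop_size), function(i) objective(pos[i, ]), numeric(1))
  if (any(!is.finite(fit))) {
    stop_invalid("objective returned a non-finite value on the initial population")
  }
  k <- which.min(fit)
  list(position = pos, fitness = fit,
       best_position = pos[k, ], best_fitness = fit[k],
       iteration = 0L, a = 2, max_iter = max_iter, spiral_b = spiral_b,
       lower = lower, upper = upper, history = numeric(0))
}

# One WOA generation: per agent draw p (and l or A, C), apply the spiral,
# encircling or exploration rule, clamp to the box, re-evaluate, then update
# the elitist best and the decay coefficient.  The exploration switch uses the
# first component of the freshly drawn A vector.
woa_step <- function(state, objective) {
  n <- nrow(state$position)
  d <- ncol(state$position)
  for (i in seq_len(n)) {
    x <- state$position[i, ]
    p <- runif(1)
    if (p >= 0.5) {
      l <- runif(1, -1, 1)
      newx <- woa_spiral(x, state$best_position, state$spiral_b, l)
    } else {
      co <- woa_coefficients(state$a, d)
      if (abs(co$A[1L]) < 1) {
        newx <- woa_encircle(x, state$best_position, co$A, co$C)
      } else {
        j <- sample.int(n, 1L)
        newx <- woa_explore(x, state$position[j, ], co$A, co$C)
      }
    }
    newx <- pmin(pmax(newx, state$lower), state$upper)
    f <- objective(newx)
    if (is.finite(f)) {
      state$position[i, ] <- newx
      state$fitness[i] <- f
    } else {
      woacnn_log("agent %d: non-finite objective value, position kept", i)
    }
  }
  if (min(state$fitness) < state$best_fitness) {
    k <- which.min(state$fitness)
    state$best_fitness <- state$fitness[k]
    state$best_position <- state$position[k, ]
  }
  state$iteration <- state$iteration + 1L
  state$a <- woa_decay(state$iteration, state$max_iter)
  state$history <- c(state$history, state$best_fitness)
  state
}

#' Minimize a function with the whale optimization algorithm
#'
#' Runs the elitist WOA on a box-constrained continuous objective.  The swarm
#' is initialized uniformly inside the box; at each generation every agent
#' moves by the spiral rule (probability 1/2) or, depending on the magnitude
#' of the coefficient `A`, by encircling the best solution or by exploring
#' toward a random agent.  Positions are clamped to the bounds, the best-ever
#' solution is retained (so the fitness history is monotone non-increasing),
#' and the exploration pressure decays linearly via [woa_decay()].
#'
#' @param objective Function mapping a numeric vector to a finite scalar to
#'   be minimized.
#' @param lower,upper Numeric vectors of box bounds (equal length, elementwise
#'   `lower < upper`).
#' @param pop_size Number of search agents (>= 2).
#' @param max_iter Number of generations.
#' @param spiral_b Logarithmic spiral shape constant (> 0).
#' @param seed Optional integer seed; when given, the run is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @return An object of class `"woa"`: a list with elements `par` (best
#'   position), `value` (best fitness), `history` (best fitness after each
#'   generation), `initial` (the evaluated starting population), `population`
#'   and `fitness` (final swarm), and the call settings.
#' @examples
#' fit <- woa(function(x) sum(x^2), lower = rep(-5, 2), upper = rep(5, 2),
#'            pop_size = 20, max_iter = 50, seed = 1)
#' fit$value
#' @seealso [plot.woa()] for the convergence trace.
#' @export
woa <- function(objective, lower, upper, pop_size = 30, max_iter = 100,
                spiral_b = 1, seed = NULL) {
  if (!is.function(objective)) stop_invalid("objective must be a function")
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) == 0L || length(lower) != length(upper)) {
    stop_invalid("lower and upper bounds must be non-empty vectors of equal length")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || !all(lower < upper)) {
    stop_invalid("bounds must be finite with lower < upper elementwise")
  }
  if (!is_count(pop_size, 2L)) stop_invalid("pop_size must be an integer >= 2")
  if (!is_count(max_iter, 1L)) stop_invalid("max_iter must be an integer >= 1")
  if (!is_number(spiral_b) || spiral_b <= 0) stop_invalid("spiral_b must be > 0")

  run <- function() {
    state <- woa_init(objective, lower, upper, pop_size, max_iter, spiral_b)
    initial <- list(position = state$position, fitness = state$fitness,
                    best_position = state$best_position,
                    best_fitness = state$best_fitness)
    for (t in seq_len(max_iter)) {
      state <- woa_step(state, objective)
    }
    list(state = state, initial = initial)
  }
  res <- with_seed_if(seed, run())

  structure(list(
    par = res$state$best_position,
    value = res$state$best_fitness,
    history = res$state$history,
    initial = res$initial,
    population = res$state$position,
    fitness = res$state$fitness,
    pop_size = pop_size,
    max_iter = max_iter,
    spiral_b = spiral_b,
    seed = seed
  ), class = "woa")
}

#' @export
print.woa <- function(x, ...) {
  cat("Whale optimization algorithm run\n")
  cat(sprintf("  dimension: %d   agents: %d   iterations: %d\n",
              length(x$par), x$pop_size, x$max_iter))
  cat(sprintf("  best fitness: %.6g\n", x$value))
  if (length(x$par) <= 8) {
    cat("  best position:", paste(signif(x$par, 5), collapse = " "), "\n")
  }
  invisible(x)
}

#' Plot the WOA convergence trace
#'
#' @param x A `"woa"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.woa <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "iteration", ylab = "best fitness",
                 main = "WOA convergence", ...)
  invisible(x)
}

#' Write an optimizer trace as CSV
#'
#' Dumps the per-iteration best fitness of a [woa()] run with columns
#' `iteration` and `best_fitness`.
#'
#' @param x A `"woa"` object (or any object with a `history` element).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_woa_trace <- function(x, path) {
  write.csv(data.frame(iteration = seq_along(x$history),
                       best_fitness = x$history),
            path, row.names = FALSE)
  invisible(path)
}
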