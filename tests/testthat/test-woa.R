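test_that("decay schedule is exactly linear from 2 to 0", {
  expect_identical(woa_decay(0, 100), 2)
  expect_identical(woa_decay(100, 100), 0)
  expect_identical(woa_decay(50, 100), 1)
  t_max <- 37
  a <- vapply(0:t_max, woa_decay, numeric(1), t_max = t_max)
  expect_equal(a, 2 * (1 - (0:t_max) / t_max))
  expect_true(all(diff(a) < 0))
  expect_error(woa_decay(5, 0), "t_max")
  expect_error(woa_decay(-1, 10), "t")
  expect_error(woa_decay(11, 10), "t")
})

test_that("coefficient vectors respect their ranges and edge cases", {
  co <- withr::with_seed(1, woa_coefficients(0, 5))
  expect_equal(co$A, rep(0, 5))
  for (a in c(0.3, 1, 2)) {
    co <- woa_coefficients(a, 200)
    expect_true(all(abs(co$A) <= a))
    expect_true(all(co$C >= 0 & co$C <= 2))
  }
  expect_error(woa_coefficients(2.5, 3), "a must")
})

test_that("position updates match hand-evaluated examples", {
  # encircling
  expect_equal(woa_encircle(c(1, 2), c(1, 2), A = c(3, 3), C = c(1, 1)), c(1, 2))
  expect_equal(woa_encircle(c(0.3, -2), c(1, 2), A = c(0, 0), C = c(0.7, 1.3)), c(1, 2))
  expect_equal(woa_encircle(0, 1, A = 0.5, C = 1), 0.5)
  # spiral
  expect_equal(woa_spiral(c(4, 4), c(4, 4), b = 1, l = 0.3), c(4, 4))
  expect_equal(woa_spiral(0, 2, b = 1, l = 0), 4)          # e^0 cos 0 = 1
  expect_equal(woa_spiral(0, 1, b = 1, l = 0.5), exp(0.5) * cos(pi) + 1,
               tolerance = 1e-12)
  # exploration
  expect_equal(woa_explore(c(5, 5), c(5, 5), A = c(2, 2), C = c(1, 1)), c(5, 5))
  expect_equal(woa_explore(c(9), c(3), A = c(0), C = c(2)), 3)
  expect_equal(woa_explore(1, 3, A = 1, C = 1), 1)
  expect_error(woa_encircle(1:2, 1:3, 1:2, 1:2), "equal length")
  expect_error(woa_spiral(1, 2, b = 1, l = 1.5), "l must")
})

test_that("optimizer converges on the sphere and a constant objective", {
  fit <- woa(function(x) sum(x^2), rep(-5, 2), rep(5, 2),
             pop_size = 20, max_iter = 200, seed = 3)
  expect_lt(fit$value, 1e-4)
  expect_length(fit$history, 200)
  expect_lt(fit$history[200], fit$history[1])

  const <- woa(function(x) 7.5, -1, 1, pop_size = 5, max_iter = 10, seed = 1)
  expect_identical(const$value, 7.5)
})

test_that("elitism, bounds, and determinism hold across seeds and objectives", {
  objectives <- list(function(x) sum(x^2),
                     function(x) sum(abs(x)) + 3,
                     function(x) sin(x[1]) * cos(x[2]))
  for (s in 1:4) {
    for (obj in objectives) {
      fit <- woa(obj, c(-4, -4), c(4, 4), pop_size = 8, max_iter = 40, seed = s)
      expect_true(all(diff(fit$history) <= 0))
      expect_true(all(fit$population >= -4 & fit$population <= 4))
      expect_equal(fit$value, min(fit$history))
    }
  }
  h1 <- woa(function(x) sum(x^2), rep(-3, 3), rep(3, 3), pop_size = 12,
            max_iter = 60, seed = 99)
  h2 <- woa(function(x) sum(x^2), rep(-3, 3), rep(3, 3), pop_size = 12,
            max_iter = 60, seed = 99)
  expect_identical(h1$history, h2$history)
  expect_identical(h1$par, h2$par)
})

test_that("a non-finite objective value leaves the agent in place", {
  # objective is finite on the initial population, then returns NaN in a
  # sub-region; agents stepping there must keep their previous position
  obj <- function(x) if (x[1] < 0) NaN else x[1]^2
  fit <- woa(obj, lower = 0.5, upper = 2, pop_size = 6, max_iter = 30, seed = 2)
  expect_true(all(is.finite(fit$fitness)))
  expect_true(all(diff(fit$history) <= 0))
})

test_that("optimizer matches an exhaustive 1-D grid scan", {
  f <- function(x) sin(x) + sin(10 * x / 3)      # multimodal on [2.7, 7.5]
  grid <- seq(2.7, 7.5, length.out = 2000)
  x_star <- grid[which.min(f(grid))]
  cell <- grid[2] - grid[1]
  hits <- vapply(1:20, function(s) {
    fit <- woa(function(x) f(x[1]), 2.7, 7.5, pop_size = 15, max_iter = 60, seed = s)
    abs(fit$par - x_star) <= cell
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("bad arguments and trace output behave", {
  expect_error(woa(function(x) 1, numeric(0), numeric(0)), "bounds")
  expect_error(woa(function(x) 1, 1, 0), "lower < upper")
  expect_error(woa(function(x) 1, 0, 1, pop_size = 1), "pop_size")
  fit <- woa(function(x) sum(x^2), -1, 1, pop_size = 4, max_iter = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_woa_trace(fit, path)
  tr <- read.csv(path)
  expect_identical(names(tr), c("iteration", "best_fitness"))
  expect_equal(tr$best_fitness, fit$history, tolerance = 1e-12)
})
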