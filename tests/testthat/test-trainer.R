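test_that("the 70/10/20 split is exact, disjoint, exhaustive, reproducible", {
  ds <- generate_dataset(100, lesion_params(), seed = 1)
  sp <- split_dataset(ds, seed = 2)
  tb <- table(sp$split)
  expect_identical(as.integer(tb[c("train", "validation", "test")]),
                   c(70L, 10L, 20L))
  sp2 <- split_dataset(ds, seed = 2)
  expect_identical(sp$split, sp2$split)
  expect_false(identical(sp$split, split_dataset(ds, seed = 3)$split))

  ds10 <- generate_dataset(10, lesion_params(), seed = 1)
  tb10 <- table(split_dataset(ds10, seed = 1)$split)
  expect_identical(as.integer(tb10[c("train", "validation", "test")]),
                   c(7L, 1L, 2L))
})

test_that("splits partition the index set for arbitrary sizes", {
  set.seed(11)
  for (n in sample(10:120, 6)) {
    ds <- generate_dataset(n, lesion_params(image_size = c(6, 6)), seed = n)
    sp <- split_dataset(ds, seed = n)
    expect_identical(sort(unique(sp$split)), c("test", "train", "validation"))
    expect_identical(length(sp$split), n)
    expect_false(anyNA(sp$split))
  }
  expect_error(split_dataset(generate_dataset(9, lesion_params(), seed = 1)),
               "too small")
  expect_error(split_dataset(generate_dataset(20, lesion_params(), seed = 1),
                             train = 0.5, validation = 0.2, test = 0.2),
               "sum to 1")
})

test_that("weight fitness at the zero position equals n * log(M) exactly", {
  spec <- tiny_spec(8)
  ds <- generate_dataset(14, lesion_params(image_size = c(8, 8)), seed = 3)
  ds$split <- rep("train", 14)
  prob <- weight_search_problem(spec, ds, fitness = "xent", gamma = 0)
  f0 <- evaluate_weight_fitness(numeric(spec$n_params), prob)
  expect_identical(f0, 14 * log(2))
  # determinism: bit-equal across calls
  pos <- withr::with_seed(4, runif(spec$n_params, -1, 1))
  expect_identical(evaluate_weight_fitness(pos, prob),
                   evaluate_weight_fitness(pos, prob))
  expect_error(evaluate_weight_fitness(numeric(3), prob), "length")
})

test_that("the fitness surface minimum agrees with an exhaustive grid oracle", {
  # two free parameters: a 1-pixel single-channel input, dense(2), biases
  # pinned at zero by restricting the search to the weight coordinates
  spec <- network_spec(c(1, 1, 1), list(flatten_layer(), dense_layer(2)))
  x <- array(c(0.2, 0.4, 0.9, 0.8, 0.25, 0.85), c(1, 1, 1, 6))
  labels <- c(0L, 0L, 1L, 1L, 0L, 1L)
  ds <- labeled_dataset(x, labels, split = rep("train", 6))
  prob <- weight_search_problem(spec, ds, fitness = "mse", bounds_halfwidth = 20)
  obj2 <- function(w) evaluate_weight_fitness(c(w[1], w[2], 0, 0), prob)
  g <- seq(-20, 20, length.out = 161)
  surf <- outer(g, g, Vectorize(function(a, b) obj2(c(a, b))))
  best <- arrayInd(which.min(surf), dim(surf))
  grid_min <- c(g[best[1]], g[best[2]])
  # continuous refinement from the grid minimum must stay within one cell
  ref <- optim(grid_min, obj2, method = "BFGS")
  cell <- g[2] - g[1]
  expect_lt(max(abs(ref$par - grid_min)), cell)
  expect_lte(ref$value, min(surf))
  # WOA restricted to the same 2-D surface finds the same basin
  fit <- woa(obj2, c(-20, -20), c(20, 20), pop_size = 15, max_iter = 80, seed = 1)
  expect_lt(fit$value, min(surf) + 1e-3)
})

test_that("WOA weight training is elitist, reproducible, beats its own start", {
  spec <- tiny_spec(8)
  ds <- split_dataset(generate_dataset(30, lesion_params(image_size = c(8, 8)),
                                       seed = 5), seed = 5)
  prob <- weight_search_problem(spec, ds)
  r1 <- woa_train_weights(prob, pop_size = 8, max_iter = 25, seed = 6)
  r2 <- woa_train_weights(prob, pop_size = 8, max_iter = 25, seed = 6)
  expect_identical(r1$history, r2$history)
  expect_identical(flatten_params(r1$params), flatten_params(r2$params))
  expect_true(all(diff(r1$history) <= 0))
  expect_lte(r1$history[length(r1$history)], r1$initial_fitness)
  final_fit <- evaluate_weight_fitness(flatten_params(r1$params), prob)
  init_fit <- evaluate_weight_fitness(flatten_params(r1$initial_params), prob)
  expect_lte(final_fit, init_fit)
})

test_that("hyperparameter decoding rounds, clamps, and is idempotent", {
  expect_identical(decode_hyper_genes(c(3.6, 9.4), 2, 8), c(4L, 8L))
  expect_identical(decode_hyper_genes(c(1.1, 2.5, 7.99), 2, 8), c(2L, 2L, 8L))
  set.seed(12)
  for (i in 1:20) {
    pos <- runif(10, 0, 12)
    genes <- decode_hyper_genes(pos, 2, 8)
    expect_identical(decode_hyper_genes(as.numeric(genes), 2, 8), genes)
    expect_true(all(genes >= 2L & genes <= 8L))
  }
  expect_error(decode_hyper_genes(c(3, 3), lower = 1), "minimum of 2")
})

test_that("a collapsed hyperparameter space returns its only configuration", {
  ds <- split_dataset(generate_dataset(30, lesion_params(image_size = c(12, 12)),
                                       seed = 7), seed = 7)
  point <- c(3, 2, 3, 2, 2, 2, 2, 2, 2, 2)
  hs <- woa_search_hyperparams(ds, lower = point, upper = point,
                               pop_size = 3, max_iter = 2,
                               inner_bp_iterations = 3, seed = 1)
  expect_identical(hs$genes, as.integer(point))
  expect_true(is.finite(hs$value))
})

test_that("hyperparameter search recovers the exhaustively best architecture", {
  # one free gene (the first pooling window, 2..5); every configuration is
  # evaluated exhaustively as the oracle, and the search must return the best
  # one in >= 9 of 10 seeds
  ds <- split_dataset(generate_dataset(40, lesion_params(image_size = c(12, 12)),
                                       seed = 9), seed = 9)
  lo <- c(3, 2, 3, 2, 2, 2, 2, 2, 2, 2)
  hi <- c(3, 2, 3, 2, 5, 2, 2, 2, 2, 2)
  cfg <- training_config(bp_iterations = 8, seed = 0)
  shape <- dim(ds$images)[1:3]
  fvals <- vapply(2:5, function(g) {
    genes <- lo; genes[5] <- g
    woacnn:::hyper_fitness(genes, ds, cfg, shape)
  }, numeric(1))
  expect_true(is.finite(min(fvals)))
  wins <- vapply(1:10, function(s) {
    hs <- woa_search_hyperparams(ds, lower = lo, upper = hi, pop_size = 4,
                                 max_iter = 4, inner_bp_iterations = 8,
                                 seed = s, config = cfg)
    hs$value <= min(fvals) + 1e-12
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("invalid architectures are penalised and never win over valid ones", {
  ds <- split_dataset(generate_dataset(20, lesion_params(image_size = c(8, 8)),
                                       seed = 10), seed = 10)
  cfg <- training_config(bp_iterations = 2, seed = 0)
  # pooling to nothing: an 8x8 input cannot survive conv(3) pool(4) conv(2)
  bad <- c(3, 2, 2, 2, 4, 2, 2, 2, 2, 2)
  expect_identical(woacnn:::hyper_fitness(bad, ds, cfg, c(8, 8, 3)), Inf)
  hs <- woa_search_hyperparams(ds, lower = c(3, 2, 2, 2, 2, 2, 2, 2, 2, 2),
                               upper = c(3, 2, 2, 2, 4, 2, 2, 2, 2, 2),
                               pop_size = 4, max_iter = 3,
                               inner_bp_iterations = 2, seed = 2, config = cfg)
  expect_true(is.finite(hs$value))
  expect_false(hs$genes[5] == 4L)
})
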