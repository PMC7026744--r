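# Coupling of the WOA optimizer to the CNN: the random 70/10/20 splitting
# protocol, direct weight-and-bias optimization (the network's full parameter
# vector is one search agent), and discrete hyperparameter search (a
# 10-integer agent decoded to an architecture and scored by a short inner
# backpropagation run).

#' Randomly split a dataset into train / validation / test
#'
#' Sizes are floor-based on the validation and test ratios with the remainder
#' assigned to training, so the default 0.7/0.1/0.2 split of 100 samples is
#' exactly 70/10/20.  Assignment is a seeded random permutation: splits are
#' disjoint, exhaustive, and reproducible.
#'
#' @param data A `"labeled_dataset"` with at least 10 samples.
#' @param train,validation,test Positive ratios summing to 1.
#' @param seed Optional integer seed.
#' @return The dataset with its `split` tags set.
#' @export
split_dataset <- function(data, train = 0.7, validation = 0.1, test = 0.2,
                          seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  ratios <- c(train, validation, test)
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop_invalid("split ratios must be positive and sum to 1")
  }
  n <- data$n
  if (n < 10L) stop_invalid("dataset too small to split (n = %d, need >= 10)", n)
  n_val <- floor(n * validation)
  n_test <- floor(n * test)
  n_train <- n - n_val - n_test
  if (n_val < 1L || n_test < 1L) {
    stop_invalid("split ratios leave an empty validation or test set for n = %d", n)
  }
  perm <- with_seed_if(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "validation"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  data$split <- split
  data
}

#' Define a weight/bias search problem for the WOA
#'
#' Fixes the architecture and the training data and exposes the network's
#' full parameter vector as a box-bounded continuous search space of
#' dimension `spec$n_params`, searched in `[-bounds_halfwidth,
#' +bounds_halfwidth]` per coordinate.  The im2col patch matrix of a leading
#' convolution is precomputed once, since the images never change across
#' fitness evaluations.
#'
#' @param spec A `"network_spec"`.
#' @param data A `"labeled_dataset"`; the `train` view defines the fitness.
#' @param fitness `"xent"` for the penalised cross-entropy loss or `"mse"`
#'   for the mean squared error between one-hot targets and class
#'   probabilities.
#' @param gamma Weight-penalty coefficient for the `"xent"` fitness.
#' @param bounds_halfwidth Half-width of the search box (> 0).
#' @return An object of class `"weight_search_problem"`.
#' @export
weight_search_problem <- function(spec, data, fitness = c("xent", "mse"),
                                  gamma = 0, bounds_halfwidth = 1) {
  stopifnot(inherits(spec, "network_spec"), inherits(data, "labeled_dataset"))
  fitness <- match.arg(fitness)
  if (!is_number(bounds_halfwidth) || bounds_halfwidth <= 0) {
    stop_invalid("bounds_halfwidth must be > 0")
  }
  view <- dataset_view(data, "train")
  x <- as_image_batch(view$images, spec)
  patches <- if (spec$layers[[1L]]$type == "conv") {
    conv_patches(x, spec$layers[[1L]]$kernel_size)
  }
  structure(list(spec = spec, x = x, targets = view$targets, n = view$n,
                 fitness = fitness, gamma = gamma,
                 halfwidth = bounds_halfwidth,
                 lower = rep(-bounds_halfwidth, spec$n_params),
                 upper = rep(bounds_halfwidth, spec$n_params),
                 patches = patches),
            class = "weight_search_problem")
}

#' Fitness of a flat parameter vector
#'
#' Unflattens the position into network parameters, scores the problem's
#' training view with one forward pass, and returns the configured fitness.
#' Deterministic: identical positions give bit-identical values.
#'
#' @param position Numeric vector of length `spec$n_params`.
#' @param problem A [weight_search_problem()].
#' @return The scalar fitness (to be minimized).
#' @export
evaluate_weight_fitness <- function(position, problem) {
  stopifnot(inherits(problem, "weight_search_problem"))
  params <- unflatten_params(position, problem$spec)
  probs <- forward_batch(problem$spec, params, problem$x,
                         first_conv_patches = problem$patches)$probs
  if (problem$fitness == "xent") {
    cross_entropy_loss(t(probs), problem$targets, params, problem$gamma)
  } else {
    mse_error(t(probs), problem$targets)
  }
}

#' Train network weights and biases with the WOA
#'
#' Runs [woa()] over [evaluate_weight_fitness()] and unflattens the best
#' position found.
#'
#' @param problem A [weight_search_problem()].
#' @param pop_size,max_iter,spiral_b,seed Passed to [woa()].
#' @return A list with `params` (best `"network_params"`), `history`
#'   (best fitness per iteration), `initial_params` (the best member of the
#'   starting population, for untrained-baseline comparisons), and the full
#'   `"woa"` result as `optim`.
#' @export
woa_train_weights <- function(problem, pop_size = 30, max_iter = 150,
                              spiral_b = 1, seed = NULL) {
  stopifnot(inherits(problem, "weight_search_problem"))
  res <- woa(function(x) evaluate_weight_fitness(x, problem),
             lower = problem$lower, upper = problem$upper,
             pop_size = pop_size, max_iter = max_iter,
             spiral_b = spiral_b, seed = seed)
  list(params = unflatten_params(res$par, problem$spec),
       history = res$history,
       initial_params = unflatten_params(res$initial$best_position, problem$spec),
       initial_fitness = res$initial$best_fitness,
       optim = res)
}

# ---- hyperparameter search -------------------------------------------------

#' Decode a continuous WOA position into integer hyperparameter genes
#'
#' Round-then-clamp per component: 3.6 with bounds `[2, 8]` decodes to 4, 9.4
#' to 8.  Decoding is idempotent (integer genes decode to themselves).
#'
#' @param position Numeric vector.
#' @param lower,upper Integer gene bounds (scalars or vectors; the lower bound
#'   must respect the pooling minimum of 2).
#' @return An integer vector of genes.
#' @export
decode_hyper_genes <- function(position, lower = 2, upper = 8) {
  lower <- as.integer(round(lower))
  upper <- as.integer(round(upper))
  if (any(lower < 2L)) stop_invalid("hyperparameter genes have a minimum of 2")
  as.integer(pmin(pmax(round(position), lower), upper))
}

#' Build an architecture from a 10-integer hyperparameter agent
#'
#' Gene mapping: genes 1-2 are the kernel sizes of two convolution layers,
#' genes 3-4 their kernel counts, genes 5-6 the two pooling windows, gene 7 a
#' width multiplier for a hidden dense layer (`gene7 * num_classes` units),
#' and genes 8-10 are reserved.  The decoded stack is conv/relu/pool,
#' conv/relu/pool, flatten, dense/relu, dense(num_classes).
#'
#' @param genes Integer vector of length 10 (each gene >= 2).
#' @param input_shape Input image shape `(h, w, c)`.
#' @param num_classes Number of classes.
#' @return A `"network_spec"`, or an error when the genes describe an
#'   architecture that does not fit the input (kernel or window larger than
#'   the running feature map).
#' @export
hyper_genes_to_spec <- function(genes, input_shape = c(16, 16, 3),
                                num_classes = 2) {
  genes <- as.integer(genes)
  if (length(genes) != 10L || any(genes < 2L)) {
    stop_invalid("a hyperparameter agent is 10 integers, each >= 2")
  }
  network_spec(input_shape, list(
    conv_layer(genes[1], genes[3]), relu_layer(), maxpool_layer(genes[5]),
    conv_layer(genes[2], genes[4]), relu_layer(), maxpool_layer(genes[6]),
    flatten_layer(),
    dense_layer(genes[7] * num_classes), relu_layer(),
    dense_layer(num_classes)))
}

# Validation error rate (1 - accuracy) of an architecture trained briefly by
# backpropagation; +Inf for architectures that do not fit the input.  The
# weight initialisation is seeded from the config so the fitness is a pure
# function of the genes.
hyper_fitness <- function(genes, data, config, input_shape, num_classes = 2) {
  spec <- tryCatch(hyper_genes_to_spec(genes, input_shape, num_classes),
                   error = function(e) NULL)
  if (is.null(spec)) {
    woacnn_log("genes [%s]: invalid architecture, +Inf penalty",
               paste(genes, collapse = " "))
    return(Inf)
  }
  params <- init_network_params(spec, seed = config$seed)
  params <- bp_train(spec, params, data, config)
  val <- dataset_view(data, "validation")
  probs <- cnn_forward(spec, params, val$images)
  pred <- as.integer(probs[, "cancer"] > probs[, "healthy"])
  mean(pred != val$labels)
}

#' Search CNN hyperparameters with the WOA
#'
#' Each search agent is a 10-integer architecture description (see
#' [hyper_genes_to_spec()]).  The WOA works on the continuous relaxation;
#' positions are decoded by round-and-clamp, each decoded architecture is
#' trained on the training split by a short backpropagation run, and its
#' validation error rate (1 - accuracy) is the fitness.  Architectures that
#' do not fit the input receive an infinite penalty and can never be returned
#' while any valid architecture exists.
#'
#' @param data A split `"labeled_dataset"`.
#' @param lower,upper Gene bounds (scalars or length-10 vectors; minimum 2).
#' @param pop_size,max_iter,seed WOA settings.
#' @param inner_bp_iterations Backpropagation steps per fitness evaluation.
#' @param config Optional [training_config()] for the inner runs (its
#'   `bp_iterations` is overridden by `inner_bp_iterations`).
#' @return A list with `genes` (best agent), `value` (its validation error
#'   rate), `spec` (the decoded architecture), and the `"woa"` result as
#'   `optim`.
#' @export
woa_search_hyperparams <- function(data, lower = 2, upper = 8,
                                   pop_size = 10, max_iter = 10,
                                   inner_bp_iterations = 30,
                                   seed = NULL, config = training_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!any(data$split == "validation", na.rm = TRUE)) {
    stop_invalid("hyperparameter search needs a validation split; run split_dataset() first")
  }
  if (!is_count(inner_bp_iterations, 1L)) {
    stop_invalid("inner_bp_iterations must be >= 1")
  }
  config$bp_iterations <- as.integer(inner_bp_iterations)
  if (is.null(config$seed)) config$seed <- if (is.null(seed)) 0L else seed
  lower <- rep_len(as.numeric(lower), 10L)
  upper <- rep_len(as.numeric(upper), 10L)
  if (any(lower < 2)) stop_invalid("gene lower bounds must be >= 2")
  input_shape <- dim(data$images)[1:3]
  memo <- new.env(parent = emptyenv())  # fitness is pure in the genes
  objective <- function(position) {
    genes <- decode_hyper_genes(position, lower, upper)
    key <- paste(genes, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- hyper_fitness(genes, data, config, input_shape)
    memo[[key]] <- f
    f
  }
  # the optimizer needs finite fitnesses; an invalid architecture gets a huge
  # finite penalty, which still can never beat a valid one (error rate <= 1)
  objective_safe <- function(position) {
    f <- objective(position)
    if (is.finite(f)) f else 1e6
  }
  res <- woa(objective_safe, lower = lower - 0.49, upper = upper + 0.49,
             pop_size = pop_size, max_iter = max_iter, seed = seed)
  genes <- decode_hyper_genes(res$par, lower, upper)
  value <- objective(genes)
  list(genes = genes, value = value,
       spec = tryCatch(hyper_genes_to_spec(genes, input_shape),
                       error = function(e) NULL),
       optim = res)
}
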