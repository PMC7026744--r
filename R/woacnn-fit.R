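# The user-facing model interface: one fitting function covering the three
# training modes (WOA on weights, backpropagation baseline, WOA on
# hyperparameters), returning a classed model object with the usual methods.

#' Fit a whale-optimized CNN lesion classifier
#'
#' Trains a small two-class CNN on a labeled image dataset in one of three
#' modes:
#' \describe{
#'   \item{`"woa"`}{(default) the whole weight/bias vector of a fixed
#'     architecture is one WOA search agent; the swarm minimises the training
#'     cross-entropy (or MSE) directly, with no gradient computations.}
#'   \item{`"bp"`}{full-batch gradient descent (backpropagation) on the same
#'     penalised loss.}
#'   \item{`"woa-hyper"`}{the WOA searches a 10-integer architecture
#'     encoding; each candidate is trained briefly by backpropagation and
#'     scored by validation error rate, and the best architecture is then
#'     trained by a full backpropagation run.}
#' }
#'
#' @param data A `"labeled_dataset"`; if it carries no split tags it is
#'   split 70/10/20 with [split_dataset()] using `seed`.
#' @param spec Architecture (`"network_spec"`); default
#'   [default_network_spec()] sized to the data (ignored by `"woa-hyper"`).
#' @param mode Training mode, see above.
#' @param fitness Weight-mode fitness: penalised cross-entropy (`"xent"`) or
#'   mean squared error (`"mse"`).
#' @param gamma L2 weight-penalty coefficient.
#' @param population,iterations WOA swarm size and generation count.
#' @param bounds_halfwidth Half-width of the weight search box.
#' @param learning_rate,bp_iterations Gradient-descent settings (modes
#'   `"bp"` and the final refit of `"woa-hyper"`).
#' @param inner_bp_iterations Backpropagation steps per hyperparameter
#'   fitness evaluation.
#' @param hyper_lower,hyper_upper Gene bounds for `"woa-hyper"`.
#' @param seed Integer seed; every random draw of the fit flows from it.
#' @return An object of class `"woacnn"` with the trained `spec`, `params`,
#'   the optimizer `history`, the (split) `data`, and mode-specific extras
#'   (`initial_params` for `"woa"`, `genes` for `"woa-hyper"`).  Methods:
#'   [print.woacnn()], [summary.woacnn()], [coef.woacnn()],
#'   [predict.woacnn()], [plot.woacnn()].
#' @examples
#' \donttest{
#' ds <- generate_dataset(60, lesion_params(), seed = 1)
#' fit <- woacnn(ds, mode = "woa", population = 10, iterations = 20, seed = 1)
#' summary(fit)
#' }
#' @export
woacnn <- function(data, spec = NULL,
                   mode = c("woa", "bp", "woa-hyper"),
                   fitness = c("xent", "mse"),
                   gamma = 0,
                   population = 30, iterations = 150,
                   bounds_halfwidth = 1,
                   learning_rate = 0.9, bp_iterations = 500,
                   inner_bp_iterations = 30,
                   hyper_lower = 2, hyper_upper = 8,
                   seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  mode <- match.arg(mode)
  fitness <- match.arg(fitness)
  if (all(is.na(data$split))) data <- split_dataset(data, seed = seed)
  if (is.null(spec)) {
    d <- dim(data$images)
    if (d[1] != d[2]) stop_invalid("provide a spec for non-square inputs")
    spec <- default_network_spec(d[1])
  }

  history <- numeric(0)
  extras <- list()
  if (mode == "woa") {
    problem <- weight_search_problem(spec, data, fitness = fitness,
                                     gamma = gamma,
                                     bounds_halfwidth = bounds_halfwidth)
    res <- woa_train_weights(problem, pop_size = population,
                             max_iter = iterations, seed = seed)
    params <- res$params
    history <- res$history
    extras <- list(initial_params = res$initial_params,
                   initial_fitness = res$initial_fitness)
  } else if (mode == "bp") {
    config <- training_config(gamma = gamma, learning_rate = learning_rate,
                              bp_iterations = bp_iterations, seed = seed)
    params <- init_network_params(spec, seed = seed)
    params <- bp_train(spec, params, data, config)
    history <- attr(params, "loss_history")
    attr(params, "loss_history") <- NULL
  } else {
    config <- training_config(gamma = gamma, learning_rate = learning_rate,
                              bp_iterations = inner_bp_iterations, seed = seed)
    search <- woa_search_hyperparams(data, lower = hyper_lower,
                                     upper = hyper_upper,
                                     pop_size = population,
                                     max_iter = iterations,
                                     inner_bp_iterations = inner_bp_iterations,
                                     seed = seed, config = config)
    if (is.null(search$spec)) {
      stop_invalid("hyperparameter search found no valid architecture in the given bounds")
    }
    spec <- search$spec
    final <- training_config(gamma = gamma, learning_rate = learning_rate,
                             bp_iterations = bp_iterations, seed = seed)
    params <- init_network_params(spec, seed = seed)
    params <- bp_train(spec, params, data, final)
    history <- search$optim$history
    attr(params, "loss_history") <- NULL
    extras <- list(genes = search$genes, hyper_value = search$value)
  }

  structure(c(list(call = match.call(), mode = mode, fitness = fitness,
                   spec = spec, params = params, history = history,
                   gamma = gamma, seed = seed, data = data),
              extras),
            class = "woacnn")
}

#' @export
print.woacnn <- function(x, ...) {
  cat(sprintf("WOA-trained CNN classifier (mode: %s)\n", x$mode))
  cat(sprintf("  architecture: %d layers, %d parameters, %dx%dx%d input\n",
              length(x$spec$layers), x$spec$n_params,
              x$spec$input_shape[1], x$spec$input_shape[2], x$spec$input_shape[3]))
  if (!is.null(x$genes)) {
    cat("  selected genes:", paste(x$genes, collapse = " "), "\n")
  }
  if (length(x$history)) {
    cat(sprintf("  final training fitness: %.6g after %d iterations\n",
                x$history[length(x$history)], length(x$history)))
  }
  invisible(x)
}

#' Classification metrics of a fitted model on a data split
#'
#' @param object A `"woacnn"` fit.
#' @param split Which split of the training data to score (default test).
#' @param ... Unused.
#' @return A list with the `"confusion_counts"`, the `"metric_report"`, and
#'   the split name; printed as a Table-style report.
#' @export
summary.woacnn <- function(object, split = "test", ...) {
  view <- dataset_view(object$data, split)
  probs <- cnn_forward(object$spec, object$params, view$images)
  pred <- as.integer(probs[, "cancer"] >= probs[, "healthy"])
  counts <- confusion_counts(pred, view$labels)
  structure(list(model = object, split = split, n = view$n,
                 counts = counts, metrics = performance_metrics(counts)),
            class = "summary.woacnn")
}

#' @export
print.summary.woacnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nPerformance on the %s split (n = %d):\n", x$split, x$n))
  print(x$metrics)
  invisible(x)
}

#' @export
coef.woacnn <- function(object, ...) {
  flatten_params(object$params)
}

#' Predict from a fitted WOA-CNN
#'
#' @param object A `"woacnn"` fit.
#' @param newdata A `"labeled_dataset"`, an `[H, W, C]` image, or an
#'   `[H, W, C, N]` batch.  Defaults to the model's own test split.
#' @param type `"class"` for 0/1 labels, `"prob"` for the class probability
#'   matrix, or `"mask"` for a per-pixel lesion mask of a single image (see
#'   [predict_mask()]).
#' @param ... For `type = "mask"`: `patch_size`, `stride`, `threshold`.
#' @return Labels, probabilities, or a `"mask_result"`.
#' @export
predict.woacnn <- function(object, newdata = NULL,
                           type = c("class", "prob", "mask"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- dataset_view(object$data, "test")
  images <- if (inherits(newdata, "labeled_dataset")) newdata$images else newdata
  if (type == "mask") {
    if (length(dim(images)) == 4L) {
      if (dim(images)[4] != 1L) {
        stop_invalid("type = 'mask' predicts one image at a time")
      }
      images <- array(images, dim(images)[1:3])
    }
    return(predict_mask(object$spec, object$params, images, ...))
  }
  probs <- cnn_forward(object$spec, object$params, images)
  if (is.null(dim(probs))) probs <- matrix(probs, 1L, dimnames = list(NULL, names(probs)))
  if (type == "prob") probs else as.integer(probs[, "cancer"] >= probs[, "healthy"])
}

#' Plot the training trace of a fitted WOA-CNN
#'
#' @param x A `"woacnn"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.woacnn <- function(x, ...) {
  ylab <- if (x$mode == "bp") "training loss" else "best fitness"
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "iteration", ylab = ylab,
                 main = sprintf("Training trace (%s)", x$mode), ...)
  invisible(x)
}
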