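# Loss functions: softmax cross-entropy with an optional L2 weight penalty,
# and the mean-per-sample squared error used as the simplified fitness.

as_prob_matrix <- function(x, name) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x)) stop_invalid("%s must be a vector or matrix", name)
  x
}

#' Cross-entropy loss with L2 weight penalty
#'
#' `L = -sum_j sum_i d_j(i) log z_j(i) + (gamma / 2) * sum(W^2)`, summed over
#' all samples and classes; the penalty runs over every connection weight of
#' every layer (biases are not penalised).  With `gamma = 0` this is the plain
#' cross-entropy of the predicted class probabilities.  Predicted
#' probabilities of zero at a target class are clipped to the machine epsilon
#' (and the event logged) so the loss stays finite.
#'
#' @param z Predicted probabilities, one sample per row (rows sum to 1).
#' @param d One-hot targets, congruent with `z`.
#' @param params Optional `"network_params"` whose weights enter the penalty.
#' @param gamma Penalty coefficient (>= 0).
#' @return The scalar loss (>= 0).
#' @examples
#' cross_entropy_loss(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
cross_entropy_loss <- function(z, d, params = NULL, gamma = 0) {
  z <- as_prob_matrix(z, "z")
  d <- as_prob_matrix(d, "d")
  if (!all(dim(z) == dim(d))) {
    stop_invalid("z (%dx%d) and d (%dx%d) must be congruent",
                 nrow(z), ncol(z), nrow(d), ncol(d))
  }
  if (!is_number(gamma) || gamma < 0) stop_invalid("gamma must be >= 0")
  hit <- z[d > 0]
  if (any(hit <= 0)) {
    woacnn_log("clipped %d zero probabilities at target classes", sum(hit <= 0))
  }
  ce <- -sum(d * log(pmax(z, .Machine$double.eps)) * (d > 0))
  pen <- if (gamma > 0 && !is.null(params)) {
    gamma / 2 * sum(vapply(params, function(p) sum(p$W^2), numeric(1)))
  } else 0
  ce + pen
}

#' Mean squared error between desired and observed outputs
#'
#' `E = (1/T) * sum_i sum_j (d_ji - o_ji)^2` where `T` is the number of
#' samples (rows); the inner sum runs over the output units.
#'
#' @param outputs Observed output vectors, one sample per row.
#' @param targets Desired output vectors, congruent with `outputs`.
#' @return The scalar error (>= 0, zero iff the outputs equal the targets).
#' @export
mse_error <- function(outputs, targets) {
  outputs <- as_prob_matrix(outputs, "outputs")
  targets <- as_prob_matrix(targets, "targets")
  if (!all(dim(outputs) == dim(targets))) {
    stop_invalid("outputs (%dx%d) and targets (%dx%d) must be congruent",
                 nrow(outputs), ncol(outputs), nrow(targets), ncol(targets))
  }
  sum((targets - outputs)^2) / nrow(outputs)
}
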