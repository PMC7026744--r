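# Analytic gradients and the gradient-descent (backpropagation) baseline
# trainer.  Gradients are of the *summed* penalised cross-entropy loss; the
# trainer scales its step by 1/T (samples) so the learning rate is on a
# per-sample scale and independent of the batch size.

# Scatter-add a patch-space gradient back to image space (col2im).
conv_backward_input <- function(dpatches, idx, in_dim) {
  n <- in_dim[4]
  dp <- matrix(dpatches, nrow(idx) * ncol(idx), n)
  g <- rowsum(dp, group = rep(as.vector(idx), times = 1L), reorder = TRUE)
  dx <- matrix(0, prod(in_dim[1:3]), n)
  dx[as.integer(rownames(g)), ] <- g
  array(dx, in_dim)
}

# Loss and gradients of the penalised cross-entropy over a batch.
# Returns list(loss, probs, grads) with grads shaped like params.
network_grad <- function(spec, params, x, targets, gamma = 0,
                         first_conv_patches = NULL) {
  x <- as_image_batch(x, spec)
  n <- dim(x)[4]
  fwd <- forward_batch(spec, params, x, cache = TRUE,
                       first_conv_patches = first_conv_patches)
  loss <- cross_entropy_loss(t(fwd$probs), targets, params, gamma)

  grads <- list()
  delta <- fwd$probs - t(targets)          # M x N, gradient at the logits
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    ca <- fwd$caches[[i]]
    key <- paste0("layer", i)
    if (ly$type == "dense") {
      p <- params[[key]]
      grads[[key]] <- list(W = ca$input %*% t(delta) + gamma * p$W,
                           b = rowSums(delta))
      delta <- p$W %*% delta
    } else if (ly$type == "flatten") {
      delta <- array(delta, ca$in_dim)
    } else if (ly$type == "relu") {
      delta <- delta * ca$mask
    } else if (ly$type == "maxpool") {
      dm <- matrix(0, prod(ca$in_dim[1:3]), ca$in_dim[4])
      ncell <- ncol(ca$idx)
      lin <- ca$idx[ca$amax + (rep.int(seq_len(ncell), ca$in_dim[4]) - 1L) * nrow(ca$idx)]
      flat <- lin + (rep(seq_len(ca$in_dim[4]), each = ncell) - 1L) * nrow(dm)
      dm[flat] <- as.vector(delta)
      delta <- array(dm, ca$in_dim)
    } else if (ly$type == "conv") {
      p <- params[[key]]
      d <- dim(delta)                      # Ho x Wo x F x N
      f <- d[3]
      dout <- matrix(aperm(delta, c(3, 1, 2, 4)), f, d[1] * d[2] * d[4])
      grads[[key]] <- list(
        W = array(fwd$caches[[i]]$patches %*% t(dout), dim = dim(p$W)) + gamma * p$W,
        b = rowSums(dout))
      if (i > 1L) {
        wm <- matrix(p$W, prod(dim(p$W)[1:3]), f)
        k <- dim(p$W)[1]
        idx <- conv_im2col_index(ca$in_dim[1], ca$in_dim[2], ca$in_dim[3], k)
        delta <- conv_backward_input(wm %*% dout, idx, ca$in_dim)
      }
    }
  }
  list(loss = loss, probs = fwd$probs, grads = grads)
}

#' Training configuration for the gradient-descent baseline
#'
#' @param gamma L2 weight-penalty coefficient (>= 0).
#' @param learning_rate Step size in `(0, 1]`, applied on a per-sample scale
#'   (the full-batch gradient is divided by the number of training samples).
#' @param bp_iterations Number of full-batch descent steps.
#' @param seed Optional seed controlling the weight initialisation.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(gamma = 0, learning_rate = 0.9,
                            bp_iterations = 500, seed = NULL) {
  if (!is_number(gamma) || gamma < 0) stop_invalid("gamma must be >= 0")
  if (!is_number(learning_rate) || learning_rate <= 0 || learning_rate > 1) {
    stop_invalid("learning_rate must lie in (0, 1]")
  }
  if (!is_count(bp_iterations, 0L)) stop_invalid("bp_iterations must be >= 0")
  structure(list(gamma = gamma, learning_rate = learning_rate,
                 bp_iterations = as.integer(bp_iterations), seed = seed),
            class = "training_config")
}

apply_grad_step <- function(params, grads, step) {
  for (key in names(params)) {
    params[[key]]$W <- params[[key]]$W - step * grads[[key]]$W
    params[[key]]$b <- params[[key]]$b - step * grads[[key]]$b
  }
  params
}

#' Train network parameters by full-batch gradient descent
#'
#' Plain backpropagation on the penalised cross-entropy loss.  Each step uses
#' the gradient over the whole training view scaled by `1/T`; if a step would
#' increase the loss it is retried with a halved step (the halving resets
#' after every accepted step), which guarantees the final training loss never
#' exceeds the initial one.
#'
#' @param spec A `"network_spec"`.
#' @param params Starting `"network_params"`.
#' @param data A `"labeled_dataset"`; the `train` split is used when split
#'   tags are present, otherwise the whole set.
#' @param config A [training_config()].
#' @return The trained `"network_params"`, with the per-iteration training
#'   loss attached as attribute `"loss_history"`.
#' @export
bp_train <- function(spec, params, data, config = training_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(data, "labeled_dataset"))
  view <- dataset_view(data, "train")
  n <- view$n
  if (n < 1L) stop_invalid("the training view is empty")
  x <- view$images
  targets <- view$targets
  patches <- NULL
  if (spec$layers[[1L]]$type == "conv") {
    patches <- conv_patches(as_image_batch(x, spec), spec$layers[[1L]]$kernel_size)
  }
  history <- numeric(config$bp_iterations)
  if (config$bp_iterations == 0L) {
    attr(params, "loss_history") <- history
    return(params)
  }
  g <- network_grad(spec, params, x, targets, config$gamma, patches)
  loss <- g$loss
  for (it in seq_len(config$bp_iterations)) {
    step <- config$learning_rate / n
    repeat {
      cand <- apply_grad_step(params, g$grads, step)
      gc2 <- network_grad(spec, cand, x, targets, config$gamma, patches)
      if (!is.finite(gc2$loss)) {
        stop_invalid("training loss became non-finite; the learning rate is too high")
      }
      if (gc2$loss <= loss || step < 1e-12) break
      step <- step / 2
    }
    params <- cand
    loss <- gc2$loss
    g <- gc2
    history[it] <- loss
  }
  attr(params, "loss_history") <- history
  params
}
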