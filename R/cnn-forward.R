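# Forward pass.  Batches are 4-D arrays [H, W, C, N]; convolution is valid
# (no padding) cross-correlation with stride 1, vectorised through an
# im2col/matrix-multiply formulation so that whole training sets are scored in
# a handful of BLAS calls.

# Linear indices (within one [H, W, C] image) of every kernel-sized patch:
# a (k*k*C) x (Ho*Wo) matrix, rows in column-major (di, dj, channel) order to
# match as.vector() of a [k, k, C] kernel, columns in column-major output
# position order.
conv_im2col_index <- function(H, W, C, k) {
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, `+`))
  off <- as.vector(outer(off, (0:(C - 1L)) * H * W, `+`))
  Ho <- H - k + 1L
  Wo <- W - k + 1L
  base <- as.vector(outer(seq_len(Ho), (seq_len(Wo) - 1L) * H, `+`))
  outer(off, base, `+`)
}

# Extract patches for a batch: returns a (k*k*C) x (Ho*Wo*N) matrix.
conv_patches <- function(x, k, idx = NULL) {
  d <- dim(x)
  if (is.null(idx)) idx <- conv_im2col_index(d[1], d[2], d[3], k)
  xm <- matrix(x, prod(d[1:3]), d[4])
  p <- xm[as.vector(idx), , drop = FALSE]
  matrix(p, nrow(idx), ncol(idx) * d[4])
}

# Batched convolution. W is [k, k, C, F]; returns [Ho, Wo, F, N].
# A precomputed patch matrix (for fixed inputs across many parameter
# evaluations) can be supplied to skip the gather.
conv_forward_batch <- function(x, W, b, patches = NULL) {
  d <- dim(x)
  k <- dim(W)[1]
  f <- dim(W)[4]
  Ho <- d[1] - k + 1L
  Wo <- d[2] - k + 1L
  if (is.null(patches)) patches <- conv_patches(x, k)
  wm <- matrix(W, prod(dim(W)[1:3]), f)
  out <- crossprod(wm, patches) + b          # f x (Ho*Wo*N); b recycles per column
  out <- array(out, c(f, Ho, Wo, d[4]))
  list(out = aperm(out, c(2, 3, 1, 4)), patches = patches)
}

# Pooling gather index: (w^2) x (Ho*Wo*F) linear indices into one [H, W, F]
# feature stack, plus the output dims.
pool_index <- function(H, W, Fc, w) {
  Ho <- H %/% w
  Wo <- W %/% w
  off <- as.vector(outer(0:(w - 1L), (0:(w - 1L)) * H, `+`))
  base <- as.vector(outer(seq(1L, by = w, length.out = Ho),
                          (seq(0L, by = w, length.out = Wo)) * H, `+`))
  base <- as.vector(outer(base, (0:(Fc - 1L)) * H * W, `+`))
  list(idx = outer(off, base, `+`), Ho = Ho, Wo = Wo)
}

# Batched non-overlapping max pooling with trailing-edge truncation.
# Returns the pooled maps plus the argmax bookkeeping needed for backprop.
maxpool_forward_batch <- function(x, w) {
  d <- dim(x)
  pi <- pool_index(d[1], d[2], d[3], w)
  ncell <- ncol(pi$idx)
  xm <- matrix(x, prod(d[1:3]), d[4])
  p <- xm[as.vector(pi$idx), , drop = FALSE]
  p <- matrix(p, nrow(pi$idx), ncell * d[4])
  out <- p[1L, ]
  amax <- rep(1L, length(out))
  for (r in seq_len(nrow(p))[-1L]) {
    gt <- p[r, ] > out
    out[gt] <- p[r, gt]
    amax[gt] <- r
  }
  list(out = array(out, c(pi$Ho, pi$Wo, d[3], d[4])),
       amax = amax, idx = pi$idx, in_dim = d)
}

relu_forward <- function(x) x * (x > 0)

# Column-wise numerically stable softmax for an M x N logit matrix.
softmax_cols <- function(f) {
  f <- sweep(f, 2, apply(f, 2, max), `-`)
  e <- exp(f)
  sweep(e, 2, colSums(e), `/`)
}

# Coerce an [H,W,C] image or [H,W,C,N] batch to a 4-D array, checking the
# spatial shape against a spec.
as_image_batch <- function(images, spec = NULL) {
  if (is.list(images)) {
    images <- simplify2array(images)  # [H, W, C, N]
  }
  d <- dim(images)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop_invalid("images must be an [H, W, C] array or an [H, W, C, N] batch")
  }
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  if (!is.null(spec) && !all(dim(images)[1:3] == spec$input_shape)) {
    stop_invalid("image shape %s does not match the network input shape %s",
                 paste(dim(images)[1:3], collapse = "x"),
                 paste(spec$input_shape, collapse = "x"))
  }
  images
}

# Full forward pass over a batch.  When cache = TRUE every intermediate needed
# by the backward pass is retained.  first_conv_patches short-circuits the
# im2col gather of a leading convolution layer whose input is fixed.
forward_batch <- function(spec, params, x, cache = FALSE,
                          first_conv_patches = NULL) {
  x <- as_image_batch(x, spec)
  n <- dim(x)[4]
  caches <- if (cache) vector("list", length(spec$layers))
  cur <- x
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    cur <- switch(ly$type,
      conv = {
        p <- params[[paste0("layer", i)]]
        pre <- if (i == 1L) first_conv_patches
        r <- conv_forward_batch(cur, p$W, p$b, patches = pre)
        if (cache) caches[[i]] <- list(patches = r$patches, in_dim = dim(cur))
        r$out
      },
      relu = {
        out <- relu_forward(cur)
        if (cache) caches[[i]] <- list(mask = cur > 0)
        out
      },
      maxpool = {
        r <- maxpool_forward_batch(cur, ly$window)
        if (cache) caches[[i]] <- r[c("amax", "idx", "in_dim")]
        r$out
      },
      flatten = {
        out <- matrix(cur, prod(dim(cur)[1:3]), n)
        if (cache) caches[[i]] <- list(in_dim = dim(cur))
        out
      },
      dense = {
        p <- params[[paste0("layer", i)]]
        if (cache) caches[[i]] <- list(input = cur)
        crossprod(p$W, cur) + p$b
      })
  }
  probs <- softmax_cols(cur)
  list(logits = cur, probs = probs, caches = caches)
}

#' CNN forward pass
#'
#' Runs an image (or a batch) through the network in layer order, ending in a
#' softmax over the classes.
#'
#' @param spec A `"network_spec"`.
#' @param params Matching `"network_params"`.
#' @param images An `[H, W, C]` array, an `[H, W, C, N]` batch, or a list of
#'   `[H, W, C]` arrays.
#' @return For a single image, a named probability vector of length
#'   `num_classes`; for a batch, an `N x num_classes` matrix with one row per
#'   image.  Rows sum to 1.
#' @export
cnn_forward <- function(spec, params, images) {
  single <- (is.array(images) && length(dim(images)) == 3L)
  out <- t(forward_batch(spec, params, images)$probs)
  colnames(out) <- if (spec$num_classes == 2L) c("healthy", "cancer") else
    paste0("class", seq_len(spec$num_classes))
  if (single) out[1L, ] else out
}

#' Single-layer operations
#'
#' The individual layer computations used by [cnn_forward()], exposed for
#' inspection and testing: `conv2d_forward()` is valid cross-correlation with
#' stride 1 (output side = input side - kernel side + 1, one map per kernel,
#' bias added per map); `relu()` is the elementwise `max(x, 0)`; `maxpool()`
#' keeps the maximum of each non-overlapping `window x window` block
#' (truncating rows/columns that do not fill a window); `softmax()` maps a
#' logit vector to a probability vector with max-subtraction for stability.
#'
#' @param input An `[H, W, C]` array (a matrix is treated as one channel).
#' @param kernels A `[k, k, C, F]` weight array (a matrix is treated as one
#'   single-channel kernel).
#' @param biases Numeric vector of length `F`.
#' @param x Numeric array (any shape for `relu`; `[H, W]` or `[H, W, F]` for
#'   `maxpool`).
#' @param window Pooling window (integer >= 2).
#' @param f Numeric logit vector.
#' @return The transformed array (or probability vector for `softmax`).
#' @name layer-ops
NULL

#' @rdname layer-ops
#' @export
conv2d_forward <- function(input, kernels, biases) {
  if (is.matrix(input)) dim(input) <- c(dim(input), 1L)
  if (is.matrix(kernels)) dim(kernels) <- c(dim(kernels), 1L, 1L)
  stopifnot(length(dim(input)) == 3L, length(dim(kernels)) == 4L)
  if (dim(kernels)[1] > dim(input)[1] || dim(kernels)[2] > dim(input)[2]) {
    stop_invalid("kernel (%dx%d) larger than the input map (%dx%d)",
                 dim(kernels)[1], dim(kernels)[2], dim(input)[1], dim(input)[2])
  }
  if (dim(kernels)[3] != dim(input)[3]) {
    stop_invalid("kernel channel count %d does not match input channels %d",
                 dim(kernels)[3], dim(input)[3])
  }
  x <- input
  dim(x) <- c(dim(input), 1L)
  r <- conv_forward_batch(x, kernels, biases)$out
  out <- r
  dim(out) <- if (dim(r)[3] == 1L) dim(r)[1:2] else dim(r)[1:3]
  out
}

#' @rdname layer-ops
#' @export
relu <- function(x) x * (x > 0)

#' @rdname layer-ops
#' @export
maxpool <- function(x, window) {
  if (!is_count(window, 2L)) {
    stop_invalid("pool window must be an integer >= 2 (got %s)", format(window))
  }
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  if (window > dim(x)[1] || window > dim(x)[2]) {
    stop_invalid("pool window %d exceeds the %dx%d map", window, dim(x)[1], dim(x)[2])
  }
  xb <- x
  dim(xb) <- c(dim(x), 1L)
  out <- maxpool_forward_batch(xb, window)$out
  if (was_matrix) dim(out) <- dim(out)[1:2] else dim(out) <- dim(out)[1:3]
  out
}

#' @rdname layer-ops
#' @export
softmax <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  e <- exp(f - max(f))
  e / sum(e)
}
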