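# Network architecture description and the parameter codec that maps every
# weight and bias to (and from) a single flat position vector, so a whole CNN
# can be treated as one WOA search agent.

#' Layer descriptors for [network_spec()]
#'
#' Constructors for the layer types understood by the forward pass:
#' valid cross-correlation convolution, ReLU, non-overlapping max pooling,
#' flattening, and fully connected (dense) layers.
#'
#' @param kernel_size Side length of the square convolution kernel.
#' @param filters Number of convolution kernels (output feature maps).
#' @param window Pooling window side length (>= 2; windows never overlap and
#'   trailing rows/columns that do not fill a window are dropped).
#' @param units Number of output units of a dense layer.
#' @return A layer descriptor list with a `type` field.
#' @name layers
NULL

#' @rdname layers
#' @export
conv_layer <- function(kernel_size, filters) {
  if (!is_count(kernel_size, 1L)) stop_invalid("kernel_size must be a positive integer")
  if (!is_count(filters, 1L)) stop_invalid("filters must be a positive integer")
  list(type = "conv", kernel_size = as.integer(kernel_size),
       filters = as.integer(filters))
}

#' @rdname layers
#' @export
relu_layer <- function() list(type = "relu")

#' @rdname layers
#' @export
maxpool_layer <- function(window) {
  if (!is_count(window, 2L)) {
    stop_invalid("maxpool window must be an integer >= 2 (got %s)", format(window))
  }
  list(type = "maxpool", window = as.integer(window))
}

#' @rdname layers
#' @export
flatten_layer <- function() list(type = "flatten")

#' @rdname layers
#' @export
dense_layer <- function(units) {
  if (!is_count(units, 1L)) stop_invalid("dense units must be a positive integer")
  list(type = "dense", units = as.integer(units))
}

#' Define a CNN architecture
#'
#' Validates a layer stack against an input shape, propagating feature-map
#' shapes layer by layer: convolutions are valid (unpadded) with stride 1, so
#' a kernel must fit inside the current map; pooling windows must be at least
#' 2 and no larger than the map side; the final layer must be a dense layer
#' whose unit count is the number of classes.
#'
#' @param input_shape Integer vector `(height, width, channels)`; channels
#'   defaults to 3 (RGB) when a length-2 shape is given.
#' @param layers List of layer descriptors (see [layers]).
#' @return An object of class `"network_spec"` carrying the layers, the
#'   per-layer output shapes, and the total trainable parameter count.
#' @examples
#' spec <- network_spec(c(16, 16, 3), list(
#'   conv_layer(3, 4), relu_layer(), maxpool_layer(2),
#'   flatten_layer(), dense_layer(2)))
#' spec$n_params
#' @export
network_spec <- function(input_shape, layers) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 3L)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    stop_invalid("input_shape must be (height, width, channels) with positive entries")
  }
  if (!is.list(layers) || length(layers) == 0L) {
    stop_invalid("layers must be a non-empty list of layer descriptors")
  }

  shape <- input_shape           # c(h, w, c) until flattened, then a scalar
  flat <- FALSE
  shapes <- vector("list", length(layers))
  layout <- vector("list", length(layers))  # weight/bias dims per layer
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    switch(ly$type,
      conv = {
        if (flat) stop_invalid("layer %d: conv after flatten is not supported", i)
        k <- ly$kernel_size
        if (k > shape[1] || k > shape[2]) {
          stop_invalid("layer %d: kernel size %d exceeds the %dx%d feature map",
                       i, k, shape[1], shape[2])
        }
        layout[[i]] <- list(w = c(k, k, shape[3], ly$filters), b = ly$filters)
        shape <- c(shape[1] - k + 1L, shape[2] - k + 1L, ly$filters)
      },
      relu = NULL,
      maxpool = {
        if (flat) stop_invalid("layer %d: maxpool after flatten is not supported", i)
        w <- ly$window
        if (w > shape[1] || w > shape[2]) {
          stop_invalid("layer %d: pool window %d exceeds the %dx%d feature map",
                       i, w, shape[1], shape[2])
        }
        shape <- c(shape[1] %/% w, shape[2] %/% w, shape[3])
      },
      flatten = {
        if (flat) stop_invalid("layer %d: repeated flatten", i)
        shape <- prod(shape)
        flat <- TRUE
      },
      dense = {
        if (!flat) stop_invalid("layer %d: dense requires a preceding flatten", i)
        layout[[i]] <- list(w = c(shape, ly$units), b = ly$units)
        shape <- ly$units
      },
      stop_invalid("layer %d: unknown layer type '%s'", i, ly$type)
    )
    shapes[[i]] <- shape
  }
  if (layers[[length(layers)]]$type != "dense") {
    stop_invalid("the final layer must be a dense layer over the classes")
  }
  n_params <- sum(vapply(layout, function(l) {
    if (is.null(l)) 0L else as.integer(prod(l$w) + l$b)
  }, integer(1)))

  structure(list(input_shape = input_shape, layers = layers, shapes = shapes,
                 layout = layout, num_classes = shape, n_params = n_params),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("CNN spec: %dx%dx%d input, %d classes, %d parameters\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3],
              x$num_classes, x$n_params))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$type,
      conv = sprintf("conv %dx%d, %d kernels", ly$kernel_size, ly$kernel_size, ly$filters),
      relu = "relu",
      maxpool = sprintf("maxpool %dx%d", ly$window, ly$window),
      flatten = "flatten",
      dense = sprintf("dense %d", ly$units))
    out <- x$shapes[[i]]
    cat(sprintf("  %d. %-22s -> %s\n", i, desc, paste(out, collapse = "x")))
  }
  invisible(x)
}

#' Default compact architecture for 2-class lesion images
#'
#' One 3x3 convolution with 4 kernels, ReLU, 2x2 max pooling, flatten, and a
#' dense layer over the two classes (healthy skin, lesion).  Small enough for
#' direct weight optimization by the WOA.
#'
#' @param input_side Side length of the square RGB input image.
#' @param num_classes Number of output classes.
#' @return A `"network_spec"`.
#' @export
default_network_spec <- function(input_side = 16, num_classes = 2) {
  network_spec(c(input_side, input_side, 3), list(
    conv_layer(3, 4), relu_layer(), maxpool_layer(2),
    flatten_layer(), dense_layer(num_classes)))
}

#' Initialize network weights and biases
#'
#' Weights are drawn Uniform(-0.5, 0.5) scaled by `1/sqrt(fan_in)` (fan-in is
#' the kernel volume for convolutions and the input width for dense layers);
#' biases start at zero.
#'
#' @param spec A `"network_spec"`.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A named list (class `"network_params"`) with one `list(W, b)` entry
#'   per parametric layer, named `layerK` by layer index.
#' @export
init_network_params <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed_if(seed, {
    params <- list()
    for (i in seq_along(spec$layout)) {
      lo <- spec$layout[[i]]
      if (is.null(lo)) next
      fan_in <- if (spec$layers[[i]]$type == "conv") prod(lo$w[1:3]) else lo$w[1]
      w <- array(runif(prod(lo$w), -0.5, 0.5) / sqrt(fan_in), dim = lo$w)
      params[[paste0("layer", i)]] <- list(W = w, b = numeric(lo$b))
    }
    structure(params, class = "network_params")
  })
}

#' Flatten network parameters to a single position vector
#'
#' Layer-major order, weights before biases within each layer, arrays in R's
#' column-major order.  [unflatten_params()] is the exact inverse; the round
#' trip is bit-identical in both directions.
#'
#' @param params A `"network_params"` list.
#' @return A numeric vector of all weights and biases.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params, function(p) c(as.vector(p$W), p$b)), use.names = FALSE)
}

#' Rebuild network parameters from a position vector
#'
#' @param x Numeric vector of length `spec$n_params`.
#' @param spec The `"network_spec"` describing the layout.
#' @return A `"network_params"` list.
#' @export
unflatten_params <- function(x, spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(x) != spec$n_params) {
    stop_invalid("parameter vector has length %d but the spec needs %d values",
                 length(x), spec$n_params)
  }
  params <- list()
  pos <- 0L
  for (i in seq_along(spec$layout)) {
    lo <- spec$layout[[i]]
    if (is.null(lo)) next
    nw <- prod(lo$w)
    w <- array(x[pos + seq_len(nw)], dim = lo$w)
    pos <- pos + nw
    b <- x[pos + seq_len(lo$b)]
    pos <- pos + lo$b
    params[[paste0("layer", i)]] <- list(W = w, b = b)
  }
  structure(params, class = "network_params")
}
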