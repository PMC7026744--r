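# Shared fixtures: tiny architectures, a naive convolution oracle, a random
# architecture generator for codec tests, and a memoized benchmark model so
# the expensive end-to-end fit is trained once per test run.

tiny_spec <- function(side = 8, kernels = 2) {
  network_spec(c(side, side, 3), list(
    conv_layer(3, kernels), relu_layer(), maxpool_layer(2),
    flatten_layer(), dense_layer(2)))
}

# direct loop evaluation of valid cross-correlation, independent of the
# im2col implementation under test
naive_conv <- function(x, W, b) {
  k <- dim(W)[1]
  f <- dim(W)[4]
  Ho <- dim(x)[1] - k + 1
  Wo <- dim(x)[2] - k + 1
  out <- array(0, c(Ho, Wo, f))
  for (fi in seq_len(f)) {
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        out[i, j, fi] <- sum(x[i:(i + k - 1), j:(j + k - 1), ] * W[, , , fi]) + b[fi]
      }
    }
  }
  out
}

# a random valid conv/pool/dense architecture on a random input side
random_spec <- function() {
  side <- sample(6:14, 1)
  k <- sample(2:min(4, side - 1), 1)
  f <- sample(1:4, 1)
  layers <- list(conv_layer(k, f), relu_layer())
  rem <- side - k + 1
  if (rem >= 2 && runif(1) < 0.7) {
    w <- sample(2:min(3, rem), 1)
    layers <- c(layers, list(maxpool_layer(w)))
  }
  layers <- c(layers, list(flatten_layer()))
  if (runif(1) < 0.5) {
    layers <- c(layers, list(dense_layer(sample(2:5, 1)), relu_layer()))
  }
  layers <- c(layers, list(dense_layer(2)))
  network_spec(c(side, side, 3), layers)
}

# params with all weights zero and fixed biases: the network output is then
# softmax(b) for every input, handy for forcing constant predictions
constant_bias_params <- function(spec, bias) {
  params <- init_network_params(spec, seed = 1)
  for (key in names(params)) params[[key]]$W[] <- 0
  last <- names(params)[length(params)]
  for (key in names(params)) params[[key]]$b[] <- 0
  params[[last]]$b <- bias
  params
}

# the benchmark end-to-end fit (easy synthetic set, WOA weight mode), trained
# once and reused by the learnability and mask tests
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_seed <- 42L

benchmark_fit <- function() {
  if (is.null(.benchmark_cache$fit)) {
    ds <- generate_dataset(200, lesion_params(), seed = benchmark_seed)
    ds <- split_dataset(ds, seed = benchmark_seed)
    .benchmark_cache$fit <- woacnn(ds, mode = "woa", population = 30,
                                   iterations = 150, seed = benchmark_seed)
  }
  .benchmark_cache$fit
}
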