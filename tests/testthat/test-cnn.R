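test_that("convolution matches hand examples and a naive loop oracle", {
  # identity 1x1 kernel
  x <- array(runif(5 * 5 * 3), c(5, 5, 3))
  k1 <- array(0, c(1, 1, 3, 3))
  for (c in 1:3) k1[1, 1, c, c] <- 1
  expect_equal(conv2d_forward(x, k1, rep(0, 3)), x)
  # all-zero kernels give a constant map at the bias
  k0 <- array(0, c(2, 2, 3, 2))
  out <- conv2d_forward(x, k0, c(1.5, -2))
  expect_true(all(out[, , 1] == 1.5) && all(out[, , 2] == -2))
  # 2x2 hand dot product
  expect_equal(conv2d_forward(matrix(c(1, 3, 2, 4), 2, 2),
                              matrix(c(1, 0, 0, 1), 2, 2), 0),
               matrix(5, 1, 1))
  # random case against the loop oracle
  set.seed(10)
  x <- array(rnorm(9 * 8 * 3), c(9, 8, 3))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  expect_equal(conv2d_forward(x, W, b), naive_conv(x, W, b), tolerance = 1e-12)
  # shape law and the kernel-too-large error
  expect_identical(dim(conv2d_forward(x, W, b))[1:2], c(7L, 6L))
  expect_error(conv2d_forward(array(0, c(2, 2, 3)), W, b), "larger")
})

test_that("relu is max(x, 0) and idempotent", {
  expect_identical(relu(c(-1, 2, 0)), c(0, 2, 0))
  expect_true(all(relu(-runif(10)) == 0))
  x <- array(rnorm(24), c(2, 3, 4))
  expect_identical(relu(relu(x)), relu(x))
  expect_identical(dim(relu(x)), dim(x))
})

test_that("max pooling keeps window maxima and truncates trailing edges", {
  expect_equal(maxpool(matrix(c(1, 3, 2, 4), 2, 2), 2), matrix(4, 1, 1))
  expect_equal(maxpool(matrix(1:16, 4, 4, byrow = TRUE), 2),
               matrix(c(6, 14, 8, 16), 2, 2))
  expect_equal(maxpool(matrix(7, 6, 6), 3), matrix(7, 2, 2))
  # 5x5 with window 2 drops the last row/column
  m <- matrix(seq_len(25), 5, 5)
  expect_identical(dim(maxpool(m, 2)), c(2L, 2L))
  expect_equal(max(maxpool(m, 2)), max(m[1:4, 1:4]))
  expect_error(maxpool(m, 1), ">= 2")
})

test_that("softmax is a stable probability map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(softmax(c(1, 0)), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # shift invariance and large-logit stability
  z <- softmax(c(1000, 999))
  expect_equal(z, softmax(c(1, 0)), tolerance = 1e-12)
  for (i in 1:20) {
    f <- rnorm(sample(2:6, 1), sd = 5)
    z <- softmax(f)
    expect_equal(sum(z), 1, tolerance = 1e-9)
    expect_true(all(z > 0))
  }
})

test_that("cross-entropy and MSE obey their closed forms and identities", {
  expect_identical(cross_entropy_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), c(1, 0)), log(2))
  # gamma = 0 recovers the unpenalised loss exactly; zero weights kill the penalty
  spec <- tiny_spec()
  p <- init_network_params(spec, seed = 1)
  z <- matrix(c(0.2, 0.8, 0.7, 0.3), 2, byrow = TRUE)
  d <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  expect_identical(cross_entropy_loss(z, d, p, gamma = 0),
                   cross_entropy_loss(z, d))
  pw <- sum(vapply(p, function(q) sum(q$W^2), numeric(1)))
  expect_equal(cross_entropy_loss(z, d, p, gamma = 0.4),
               cross_entropy_loss(z, d) + 0.2 * pw)
  p0 <- constant_bias_params(spec, c(0, 0))
  expect_identical(cross_entropy_loss(z, d, p0, gamma = 7),
                   cross_entropy_loss(z, d))
  # zero probability at the target class is clipped, not an error
  expect_true(is.finite(cross_entropy_loss(c(0, 1), c(1, 0))))
  # MSE
  expect_identical(mse_error(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_identical(mse_error(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), 1)
  expect_equal(mse_error(matrix(0.5, 2, 1), matrix(c(1, 0), 2, 1)), 0.25)
  expect_error(mse_error(matrix(0, 2, 2), matrix(0, 3, 2)), "congruent")
})

test_that("forward pass equals an independent layer-by-layer composition", {
  spec <- tiny_spec(8)
  p <- init_network_params(spec, seed = 5)
  img <- withr::with_seed(6, array(runif(8 * 8 * 3), c(8, 8, 3)))
  got <- cnn_forward(spec, p, img)
  manual <- softmax(as.vector(
    crossprod(p$layer5$W,
              as.vector(maxpool(relu(conv2d_forward(img, p$layer1$W, p$layer1$b)), 2))) +
      p$layer5$b))
  expect_equal(unname(got), manual, tolerance = 1e-14)
  # all-zero parameters give the uniform output
  p0 <- constant_bias_params(spec, c(0, 0))
  expect_equal(unname(cnn_forward(spec, p0, img)), c(0.5, 0.5))
  # batch rows are probability vectors
  batch <- withr::with_seed(7, array(runif(8 * 8 * 3 * 5), c(8, 8, 3, 5)))
  probs <- cnn_forward(spec, p, batch)
  expect_identical(dim(probs), c(5L, 2L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)
  expect_error(cnn_forward(spec, p, array(0, c(7, 8, 3))), "shape")
})

test_that("flatten/unflatten is an exact bijection on random architectures", {
  set.seed(123)
  for (i in 1:100) {
    spec <- random_spec()
    p <- init_network_params(spec)
    v <- flatten_params(p)
    expect_identical(length(v), as.integer(spec$n_params))
    back <- unflatten_params(v, spec)
    expect_identical(unclass(back), unclass(p))
    expect_identical(flatten_params(back), v)
  }
  # documented count for a single dense layer: 3 inputs x 2 units + 2 biases
  spec1 <- network_spec(c(1, 1, 3), list(flatten_layer(), dense_layer(2)))
  expect_identical(spec1$n_params, 8L)
  expect_error(unflatten_params(numeric(3), spec1), "length 3.*8")
})

test_that("forward output is invariant to a codec round trip", {
  spec <- tiny_spec(10)
  p <- init_network_params(spec, seed = 9)
  img <- withr::with_seed(10, array(runif(10 * 10 * 3), c(10, 10, 3)))
  p2 <- unflatten_params(flatten_params(p), spec)
  expect_identical(cnn_forward(spec, p, img), cnn_forward(spec, p2, img))
})

test_that("architecture validation rejects impossible stacks", {
  expect_error(network_spec(c(4, 4, 3), list(conv_layer(5, 2), flatten_layer(),
                                             dense_layer(2))), "kernel")
  expect_error(network_spec(c(8, 8, 3), list(conv_layer(3, 2), maxpool_layer(7),
                                             flatten_layer(), dense_layer(2))),
               "pool window")
  expect_error(maxpool_layer(1), ">= 2")
  expect_error(network_spec(c(8, 8, 3), list(conv_layer(3, 2))), "final layer")
  expect_error(network_spec(c(8, 8, 3), list(flatten_layer(), dense_layer(2),
                                             conv_layer(2, 2))), "conv after flatten")
})
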