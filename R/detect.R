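# Sliding-window mask prediction: the trained two-class patch classifier is
# swept over a full image and its lesion-class probabilities are assembled
# into a per-pixel probability map and a thresholded binary mask.

#' Extract sliding-window patches from an image
#'
#' Patches tile the image in row-major order (rows before columns, origin
#' top-left) at the given stride; the count is
#' `floor((H - patch)/stride + 1) * floor((W - patch)/stride + 1)`.
#'
#' @param image An `[H, W, C]` array.
#' @param patch_size Patch side length (<= both image sides).
#' @param stride Step between patch origins (>= 1).
#' @return A list with `patches` (`[patch, patch, C, K]` array) and `centers`
#'   (K x 2 matrix of 0-based `(row, col)` patch-center coordinates).
#' @export
extract_patches <- function(image, patch_size, stride = patch_size) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  stopifnot(length(dim(image)) == 3L)
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (!is_count(patch_size, 1L) || patch_size > min(h, w)) {
    stop_invalid("patch_size must be a positive integer <= min(image dims) = %d",
                 min(h, w))
  }
  if (!is_count(stride, 1L)) stop_invalid("stride must be a positive integer")
  r0 <- seq(1L, h - patch_size + 1L, by = stride)
  c0 <- seq(1L, w - patch_size + 1L, by = stride)
  k <- length(r0) * length(c0)
  patches <- array(0, c(patch_size, patch_size, dim(image)[3], k))
  centers <- matrix(0, k, 2, dimnames = list(NULL, c("row", "col")))
  i <- 0L
  for (r in r0) {                      # row-major: all columns of a row first
    for (cc in c0) {
      i <- i + 1L
      patches[, , , i] <- image[r:(r + patch_size - 1L),
                                cc:(cc + patch_size - 1L), , drop = FALSE]
      centers[i, ] <- c(r - 1L, cc - 1L) + (patch_size - 1) / 2
    }
  }
  list(patches = patches, centers = centers,
       patch_size = as.integer(patch_size), stride = as.integer(stride))
}

#' Predict a binary lesion mask for an image
#'
#' Scores every sliding-window patch with the classifier's lesion-class
#' probability, accumulates the scores over each patch's footprint (averaging
#' where footprints overlap), extends border pixels beyond the last scored
#' footprint with the nearest covered row/column, and thresholds the
#' resulting probability map.
#'
#' @param spec A `"network_spec"` whose input matches `patch_size`.
#' @param params Trained `"network_params"` (all values finite).
#' @param image An `[H, W, C]` array at least as large as a patch.
#' @param patch_size Patch side; defaults to the network input side.
#' @param stride Step between patches; defaults to half the patch (overlap
#'   averaging).
#' @param threshold Probability cut for the binary mask.
#' @return An object of class `"mask_result"`: `mask` (`H x W` matrix of 0 =
#'   background, 1 = cancerous region, exactly
#'   `probability_map >= threshold`), `probability_map` (`H x W`, in `[0,1]`),
#'   and the `patch_size`, `stride`, `threshold` used.
#' @export
predict_mask <- function(spec, params, image,
                         patch_size = spec$input_shape[1],
                         stride = max(1L, patch_size %/% 2L),
                         threshold = 0.5) {
  stopifnot(inherits(spec, "network_spec"))
  if (any(!vapply(params, function(p) all(is.finite(p$W)) && all(is.finite(p$b)),
                  logical(1)))) {
    stop_invalid("network parameters contain non-finite values; train the model first")
  }
  if (!is_number(threshold)) stop_invalid("threshold must be a number")
  if (patch_size != spec$input_shape[1]) {
    stop_invalid("patch_size %d does not match the network input side %d",
                 patch_size, spec$input_shape[1])
  }
  ep <- extract_patches(image, patch_size, stride)
  probs <- cnn_forward(spec, params, ep$patches)
  if (is.null(dim(probs))) probs <- matrix(probs, 1L, dimnames = list(NULL, names(probs)))
  p1 <- probs[, "cancer"]

  h <- dim(as_image_batch(image))[1]
  w <- dim(as_image_batch(image))[2]
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  origins <- ep$centers - (patch_size - 1) / 2 + 1  # back to 1-based origins
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1]
    cc <- origins[i, 2]
    rows <- r:(r + patch_size - 1L)
    cols <- cc:(cc + patch_size - 1L)
    acc[rows, cols] <- acc[rows, cols] + p1[i]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  covered_r <- max(which(rowSums(cnt) > 0))
  covered_c <- max(which(colSums(cnt) > 0))
  prob <- acc / pmax(cnt, 1)
  if (covered_r < h) prob[(covered_r + 1L):h, ] <-
    prob[rep(covered_r, h - covered_r), ]
  if (covered_c < w) prob[, (covered_c + 1L):w] <-
    prob[, rep(covered_c, w - covered_c)]
  mask <- (prob >= threshold) + 0L
  structure(list(mask = mask, probability_map = prob,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride), threshold = threshold),
            class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("Lesion mask %dx%d: %.1f%% flagged (patch %d, stride %d, threshold %.2f)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              x$patch_size, x$stride, x$threshold))
  invisible(x)
}

#' Write a mask result to disk
#'
#' The binary mask goes to `path` as a single-channel PNG with values
#' `{0, 255}`; the probability map is written alongside (suffix `_prob.png`)
#' and a CSV sidecar (suffix `_grid.csv`) records the patch grid parameters.
#'
#' @param x A `"mask_result"`.
#' @param path Output PNG path for the binary mask.
#' @param prob Also write the probability map and sidecar?
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path, prob = TRUE) {
  stopifnot(inherits(x, "mask_result"))
  png::writePNG(x$mask * 1.0, path)
  if (prob) {
    base <- sub("\\.png$", "", path)
    png::writePNG(x$probability_map, paste0(base, "_prob.png"))
    write.csv(data.frame(patch_size = x$patch_size, stride = x$stride,
                         threshold = x$threshold),
              paste0(base, "_grid.csv"), row.names = FALSE)
  }
  invisible(path)
}
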