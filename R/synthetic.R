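# Synthetic dermoscopy-like image generator.  Produces two classes: plain
# skin-textured backgrounds, and backgrounds carrying a darker irregular
# lesion blob with a known per-pixel ground-truth mask.  Every other module is
# testable against these images without any external image database.

#' Labeled image dataset container
#'
#' Bundles an image batch with one-hot class targets, optional ground-truth
#' masks, and train/validation/test split tags.
#'
#' @param images An `[H, W, C, N]` array (or list of `[H, W, C]` arrays) with
#'   values in `[0, 1]`.
#' @param labels Integer vector of length N with values 0 (healthy skin) or
#'   1 (lesion / cancer).
#' @param masks Optional `[H, W, N]` binary array of ground-truth lesion
#'   masks.
#' @param split Optional character vector of `"train"`, `"validation"`,
#'   `"test"` tags (NA when not yet split).
#' @return An object of class `"labeled_dataset"` with elements `images`,
#'   `labels`, `targets` (N x 2 one-hot matrix, columns healthy/cancer),
#'   `masks`, `split`, and `n`.
#' @export
labeled_dataset <- function(images, labels, masks = NULL, split = NULL) {
  images <- as_image_batch(images)
  n <- dim(images)[4]
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% c(0L, 1L))) {
    stop_invalid("labels must be %d values in {0, 1}", n)
  }
  targets <- cbind(healthy = as.numeric(labels == 0L),
                   cancer = as.numeric(labels == 1L))
  if (!is.null(masks)) {
    if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
    stopifnot(length(dim(masks)) == 3L, dim(masks)[3] == n)
  }
  if (is.null(split)) split <- rep(NA_character_, n)
  stopifnot(length(split) == n)
  structure(list(images = images, labels = labels, targets = targets,
                 masks = masks, split = split, n = n),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Labeled dataset: %d images of %dx%dx%d (%d lesion, %d healthy)\n",
              x$n, d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!all(is.na(x$split))) {
    tb <- table(factor(x$split, levels = c("train", "validation", "test")))
    cat(sprintf("  split: %d train / %d validation / %d test\n",
                tb[["train"]], tb[["validation"]], tb[["test"]]))
  }
  if (!is.null(x$masks)) cat("  ground-truth masks present\n")
  invisible(x)
}

#' Subset a labeled dataset by index or split tag
#'
#' @param data A `"labeled_dataset"`.
#' @param which Integer indices, or one of `"train"`, `"validation"`,
#'   `"test"`; any other string (or `NULL`) returns the full set.
#' @return A `"labeled_dataset"` restricted to the selected samples.
#' @export
dataset_view <- function(data, which = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  idx <- if (is.numeric(which)) {
    as.integer(which)
  } else if (is.character(which) && length(which) == 1L &&
             which %in% c("train", "validation", "test") &&
             any(!is.na(data$split))) {
    which(data$split == which)
  } else {
    seq_len(data$n)
  }
  labeled_dataset(data$images[, , , idx, drop = FALSE],
                  data$labels[idx],
                  if (!is.null(data$masks)) data$masks[, , idx, drop = FALSE],
                  data$split[idx])
}

#' Controls of the synthetic lesion image generator
#'
#' @param image_size `(height, width)` of the generated RGB images.
#' @param lesion_radius_range Two fractions of the image side; the two ellipse
#'   semi-axes of a lesion are drawn uniformly from this range (times the
#'   side length).
#' @param lesion_darkening Contrast offset in `[0, 1]` subtracted (with a
#'   brownish channel weighting) inside the lesion.
#' @param boundary_irregularity Amplitude (>= 0) of the smooth radial noise
#'   perturbing the lesion outline; 0 gives an exact ellipse.
#' @param skin_noise_sd Standard deviation of the Gaussian texture noise added
#'   to every pixel and channel.
#' @param class_balance Fraction of lesion-positive images in a generated
#'   dataset.
#' @param seed Optional default seed for [generate_dataset()].
#' @return A list of class `"lesion_params"`.
#' @export
lesion_params <- function(image_size = c(16, 16),
                          lesion_radius_range = c(0.15, 0.3),
                          lesion_darkening = 0.5,
                          boundary_irregularity = 0.3,
                          skin_noise_sd = 0.05,
                          class_balance = 0.5,
                          seed = NULL) {
  image_size <- as.integer(image_size)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 4L))
  if (length(lesion_radius_range) != 2L || any(lesion_radius_range < 0) ||
      lesion_radius_range[1] > lesion_radius_range[2] ||
      lesion_radius_range[2] > 0.5) {
    stop_invalid("lesion_radius_range must be increasing fractions in [0, 0.5]")
  }
  stopifnot(is_number(lesion_darkening), lesion_darkening >= 0, lesion_darkening <= 1,
            is_number(boundary_irregularity), boundary_irregularity >= 0,
            is_number(skin_noise_sd), skin_noise_sd >= 0,
            is_number(class_balance), class_balance >= 0, class_balance <= 1)
  structure(list(image_size = image_size,
                 lesion_radius_range = lesion_radius_range,
                 lesion_darkening = lesion_darkening,
                 boundary_irregularity = boundary_irregularity,
                 skin_noise_sd = skin_noise_sd,
                 class_balance = class_balance,
                 seed = seed),
            class = "lesion_params")
}

# Base skin tone (warm light skin) with small per-image jitter, and the
# channel weighting of the lesion darkening (lesions skew brown: blue drops
# least so the blob stays brownish rather than grey).
.skin_base <- c(0.87, 0.72, 0.60)
.lesion_weight <- c(0.85, 1.0, 0.75)

#' Generate one synthetic dermoscopy-like image
#'
#' The background is a jittered warm skin tone plus Gaussian texture noise,
#' clipped to `[0, 1]`.  A positive image composites a radially perturbed dark
#' ellipse, placed so the blob lies fully inside the frame; the returned mask
#' marks exactly its pixels.  Uses the current RNG stream (seed via
#' [generate_dataset()] or [withr::with_seed()]).
#'
#' @param params A [lesion_params()] object.
#' @param positive Logical: draw a lesion?
#' @return A list with `image` (`[H, W, 3]`, values in `[0, 1]`), `mask`
#'   (`H x W` binary matrix, all zero for negatives), and `label` (one-hot
#'   vector over healthy/cancer).
#' @export
generate_lesion_image <- function(params, positive) {
  stopifnot(inherits(params, "lesion_params"))
  h <- params$image_size[1]
  w <- params$image_size[2]
  side <- min(h, w)

  base <- pmin(pmax(.skin_base + rnorm(3, 0, 0.03), 0), 1)
  img <- array(rep(base, each = h * w), c(h, w, 3))
  img <- img + array(rnorm(h * w * 3, 0, params$skin_noise_sd), c(h, w, 3))

  mask <- matrix(0L, h, w)
  if (positive) {
    r <- runif(2, params$lesion_radius_range[1], params$lesion_radius_range[2]) * side
    if (any(r <= 0)) stop_invalid("positive image requested but lesion radius is 0")
    irr <- params$boundary_irregularity
    # smooth radial perturbation from a few low-order harmonics, normalised
    # so the outline stays within (1 +/- irr) times the ellipse radius
    nh <- 3L
    amp <- runif(nh)
    phase <- runif(nh, 0, 2 * pi)
    s <- function(theta) {
      v <- 0
      for (k in seq_len(nh)) v <- v + amp[k] * cos((k + 1) * theta + phase[k])
      v / max(sum(amp), 1e-12)
    }
    margin <- max(r) * (1 + irr) + 1
    cx <- if (h - 2 * margin > 0) runif(1, margin, h - margin) else (h + 1) / 2
    cy <- if (w - 2 * margin > 0) runif(1, margin, w - margin) else (w + 1) / 2
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dx <- (rows - cx) / r[1]
    dy <- (cols - cy) / r[2]
    theta <- atan2(dy, dx)
    rho <- 1 + irr * s(theta)
    inside <- (dx^2 + dy^2) <= rho^2
    mask[inside] <- 1L
    dark <- params$lesion_darkening * .lesion_weight
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- plane[inside] - dark[ch] +
        rnorm(sum(inside), 0, params$skin_noise_sd / 2)
      img[, , ch] <- plane
    }
  }
  img <- pmin(pmax(img, 0), 1)
  label <- if (positive) c(healthy = 0, cancer = 1) else c(healthy = 1, cancer = 0)
  list(image = img, mask = mask, label = label)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `floor(n * class_balance)` lesion-positive images (remainder
#' negative), shuffles them, and packs images, one-hot targets and
#' ground-truth masks into a [labeled_dataset()].  Identical seeds give
#' bit-identical pixel data.
#'
#' @param n Number of images (>= 1).
#' @param params A [lesion_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A `"labeled_dataset"` ready for [split_dataset()].
#' @examples
#' ds <- generate_dataset(20, lesion_params(), seed = 1)
#' ds
#' @export
generate_dataset <- function(n, params = lesion_params(), seed = params$seed) {
  if (!is_count(n, 1L)) stop_invalid("n must be a positive integer")
  stopifnot(inherits(params, "lesion_params"))
  with_seed_if(seed, {
    n_pos <- floor(n * params$class_balance)
    positive <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    h <- params$image_size[1]
    w <- params$image_size[2]
    images <- array(0, c(h, w, 3, n))
    masks <- array(0L, c(h, w, n))
    for (i in seq_len(n)) {
      g <- generate_lesion_image(params, positive[i])
      images[, , , i] <- g$image
      masks[, , i] <- g$mask
    }
    labeled_dataset(images, as.integer(positive), masks)
  })
}
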