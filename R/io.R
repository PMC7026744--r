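# Disk formats: the model archive (one JSON file: architecture + named
# numeric arrays) and the dataset convention (PNG images, PNG masks, CSV
# manifest), which is the package's universal dataset input so real images
# can be substituted for synthetic ones.

fmt_dbl <- function(x) sprintf("%.17g", x)   # round-trips doubles bit-exactly

spec_to_list <- function(spec) {
  list(input_shape = spec$input_shape,
       layers = lapply(spec$layers, function(ly) ly[!vapply(ly, is.null, TRUE)]))
}

spec_from_list <- function(x) {
  layers <- lapply(x$layers, function(ly) {
    switch(ly$type,
      conv = conv_layer(ly$kernel_size, ly$filters),
      relu = relu_layer(),
      maxpool = maxpool_layer(ly$window),
      flatten = flatten_layer(),
      dense = dense_layer(ly$units),
      stop_invalid("unknown layer type '%s' in model archive", ly$type))
  })
  network_spec(unlist(x$input_shape), layers)
}

#' Save a model archive
#'
#' Writes a single JSON document containing a format version, the seed, the
#' architecture, and every weight/bias array (dimensions plus values encoded
#' as full-precision decimal strings, so the read-back is bit-exact).
#'
#' @param x A `"woacnn"` fit, or a list with `spec` and `params`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(x, path) {
  spec <- x$spec
  params <- x$params
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(
    format = "woacnn-model",
    version = 1L,
    seed = if (is.null(x$seed)) NA else x$seed,
    mode = if (is.null(x$mode)) NA else x$mode,
    spec = spec_to_list(spec),
    params = lapply(params, function(p) {
      list(W = list(dim = dim(p$W), data = fmt_dbl(as.vector(p$W))),
           b = list(data = fmt_dbl(p$b)))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a model archive
#'
#' @param path Path written by [write_model()].
#' @return A list with `spec` (`"network_spec"`), `params`
#'   (`"network_params"`), `seed`, and `mode`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "woacnn-model")) {
    stop_invalid("'%s' is not a model archive", path)
  }
  spec <- spec_from_list(doc$spec)
  params <- list()
  for (key in names(doc$params)) {
    p <- doc$params[[key]]
    params[[key]] <- list(W = array(as.numeric(unlist(p$W$data)),
                                    dim = unlist(p$W$dim)),
                          b = as.numeric(unlist(p$b$data)))
  }
  class(params) <- "network_params"
  # archives store layers keyed by index; verify against the spec layout
  chk <- unflatten_params(flatten_params(params), spec)
  stopifnot(identical(lapply(chk, function(p) dim(p$W)),
                      lapply(params, function(p) dim(p$W))))
  list(spec = spec, params = params,
       seed = doc$seed, mode = doc$mode)
}

#' Write a dataset as PNG files plus a CSV manifest
#'
#' Images go to `images/NNNN.png`, ground-truth masks (when present) to
#' `masks/NNNN.png` with values `{0, 255}`, and `manifest.csv` lists
#' `filename, label, mask_filename, split` — the package's universal dataset
#' input format.
#'
#' @param data A `"labeled_dataset"`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "labeled_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  has_masks <- !is.null(data$masks)
  if (has_masks) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  fn <- sprintf("images/%04d.png", seq_len(data$n))
  mfn <- if (has_masks) sprintf("masks/%04d.png", seq_len(data$n)) else
    rep(NA_character_, data$n)
  for (i in seq_len(data$n)) {
    png::writePNG(data$images[, , , i], file.path(dir, fn[i]))
    if (has_masks) png::writePNG(data$masks[, , i] * 1.0, file.path(dir, mfn[i]))
  }
  manifest <- data.frame(filename = fn, label = data$labels,
                         mask_filename = mfn, split = data$split,
                         stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from a CSV manifest
#'
#' @param path A `manifest.csv` path (or the directory containing it); image
#'   paths in the manifest are resolved relative to the manifest.
#' @return A `"labeled_dataset"` (masks attached when every row has one).
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop_invalid("manifest not found: %s", path)
  root <- dirname(path)
  resolve <- function(f) ifelse(startsWith(f, "/"), f, file.path(root, f))
  manifest <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  n <- nrow(manifest)
  if (n == 0L) stop_invalid("empty manifest: %s", path)
  imgs <- lapply(manifest$filename, function(f) {
    img <- png::readPNG(resolve(f))
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    img[, , 1:3, drop = FALSE]   # drop any alpha channel
  })
  images <- simplify2array(imgs)
  masks <- NULL
  if (!is.null(manifest$mask_filename) && !anyNA(manifest$mask_filename)) {
    masks <- simplify2array(lapply(manifest$mask_filename, function(f) {
      m <- png::readPNG(resolve(f))
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      (m > 0.5) + 0L
    }))
  }
  split <- if (is.null(manifest$split)) NULL else as.character(manifest$split)
  labeled_dataset(images, manifest$label, masks, split)
}
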