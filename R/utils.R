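# Internal helpers shared across the package.

#' @importFrom stats runif rnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

# Evaluate `code` under a temporary seed when one is given, leaving the
# caller's RNG stream untouched; with seed = NULL the global stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Lightweight logging: messages are emitted only when options(woacnn.verbose)
# is TRUE, so numerical-edge events (clipped probabilities, rejected agents)
# are observable without polluting normal runs.
woacnn_log <- function(fmt, ...) {
  if (isTRUE(getOption("woacnn.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
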