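#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible stage seed from a global seed and a label
#'
#' One global seed drives the whole pipeline; every stage (and every
#' LIME subject, every training iteration) draws its own seed from it by
#' hashing a label, so stages can be re-run in isolation and still match
#' a full run.
#'
#' @param seed integer global seed.
#' @param label character label of the stage.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647
  h <- as.double(seed %% m)
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 2) + 1)
}

# short hex digest of an arbitrary R object (config stamping)
obj_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  m <- 2147483647
  h <- 17
  for (c in utf8ToInt(txt)) h <- (h * 31 + c) %% m
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' out of range", name), call. = FALSE)
  as.double(x)
}
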