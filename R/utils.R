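# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Folds the master seed with a sequence of integer or character keys through
#' a Lehmer-style modular recurrence, so that every sample, chromosome and
#' recursion level of the pipeline draws from its own deterministic stream.
#' The result is always in `[0, 2^31 - 2]`, safe for [set.seed()].
#'
#' @param seed Integer master seed.
#' @param ... Integer or character keys (e.g. method label, cell count,
#'   replicate index). Characters are hashed by their UTF-8 code-point sum.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  s <- as.double(seed) %% 2147483647
  for (x in keys) {
    if (is.character(x)) x <- sum(utf8ToInt(paste(x, collapse = ""))) else x <- as.double(x)
    # multiplier 48271 keeps every product below 2^53, so the arithmetic is
    # exact in doubles
    s <- (s * 48271 + x + 1) %% 2147483647
  }
  as.integer(s)
}

# Lower-median: for even n returns the smaller of the two central order
# statistics. Used for every median in the normalization module so that
# results are deterministic and a window attaining the median gets ratio
# exactly 1.
median_low <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- (n + 1L) %/% 2L
  sort(x, partial = k)[k]
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
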