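`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed
#'
#' Stages of the pipeline draw from independent, reproducible random streams.
#' Each stage gets its own seed derived from the global seed and a fixed
#' stage offset, kept inside the 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param k integer stream offset.
#' @return an integer seed.
#' @export
seed_for <- function(seed, k = 0L) {
  as.integer((as.numeric(seed) %% 1e6 * 10007 + as.numeric(k) * 7919 + 1) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)
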