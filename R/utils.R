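#' Derive a substream seed from a master seed
#'
#' Deterministically hashes a master seed together with a stream label (any
#' mix of strings and numbers) into a 31-bit integer seed, so that named
#' substreams (partitioning, per-fit chains, simulation) are mutually
#' independent of how many of the other streams are consumed.  Returns `NULL`
#' when `seed` is `NULL`.
#'
#' @param seed master integer seed or `NULL`.
#' @param ... stream labels.
#' @return An integer in `[0, 2^31 - 2]`, or `NULL`.
#' @export
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  lab <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      ""), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(lab)) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}
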