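`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantize a numeric vector through 32-bit float precision
#'
#' Surface scalar formats (curv, GIFTI float32 arrays) store single-precision
#' values; this helper reproduces that quantization in memory so round-trip
#' identities can be checked bit-exactly.
#'
#' @param x Numeric vector.
#' @return Numeric vector after a float32 write/read round trip.
#' @export
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L),
          "numeric", n = length(x), size = 4L)
}

# Derive a stream-specific seed from a base seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_binary_map <- function(x) {
  is.logical(x) || all(x %in% c(0, 1))
}
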