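#' @keywords internal
"_PACKAGE"

# 1-based closed interval helpers. All locus coordinates in this package are
# 1-based closed in the frame of the modified 45S reference; BED files are
# converted at the I/O boundary only.

interval_ok <- function(x) {
  is.numeric(x) && length(x) == 2L && !anyNA(x) && x[1] >= 1 && x[2] >= x[1]
}

interval_len <- function(x) x[2] - x[1] + 1

intervals_overlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2]
}

interval_within <- function(inner, outer) {
  inner[1] >= outer[1] && inner[2] <= outer[2]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}
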