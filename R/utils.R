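`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed affine
#' counter scheme so that toggling stages on or off does not perturb the
#' random stream of the remaining stages. The result always fits in a 32-bit
#' signed integer.
#'
#' @param seed global integer seed.
#' @param stage stage counter (small nonnegative integer).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2048 + (stage %% 2048))
}

# Fix eigenvector signs: largest-magnitude entry of each column positive.
.fix_signs <- function(V) {
  flip <- apply(V, 2L, function(col) {
    s <- col[which.max(abs(col))]
    if (s < 0) -1 else 1
  })
  sweep(V, 2L, flip, `*`)
}
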