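#' @keywords internal
#' @useDynLib alphanft, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Package-local cache (DPSS tapers etc.)
.alphanft_cache <- new.env(parent = emptyenv())

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator functions are pure in
#' (arguments, seed) and do not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying in
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
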