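#' @useDynLib glasstree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats nlminb runif setNames qgamma pgamma rgamma
#' @importFrom utils write.table packageVersion
NULL

# Round half-up to `digits` decimals. base::round() rounds half-to-even,
# which disagrees with how tree statistics are conventionally printed.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a run seed; keeps everything below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587L)
}

# Normalize taxon labels: NEXUS dialects interchange spaces and underscores.
normalize_label <- function(x) {
  x <- gsub("^'|'$", "", x)
  gsub("[[:space:]]+", "_", trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glasstree <- function(...) stop(..., call. = FALSE)
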