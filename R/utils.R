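# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not perturb the user's random stream.
#' @noRd
.with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic per-stream sub-seed, kept within the 32-bit integer range.
# `stream` separates independent consumers (permutation runs, cohorts, ...)
# so results do not depend on evaluation order or worker count.
.derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 1000003) %% 2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msgf <- function(fmt, ...) message(sprintf(fmt, ...))

# Case-normalised gene symbols: the project-wide comparison convention.
.norm_symbols <- function(x) toupper(trimws(x))

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x)
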