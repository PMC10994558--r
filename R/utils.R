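`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a master seed and an index,
# kept within 32-bit integer range.
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + as.double(index) * 7919) %% 2147483587)
}

stop_config <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}
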