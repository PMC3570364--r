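## Small internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators inside
#' the package never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_domain <- function(...) stop(..., call. = FALSE)

## FWHM of a Gaussian = 2 sqrt(2 log 2) sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
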