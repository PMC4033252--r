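#' Evaluate an expression under a local random seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded helpers never perturb global
#' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## derive a stream-specific 32-bit sub-seed from a master seed
## (double arithmetic: the product stays below 2^53, so the mod is exact)
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 97) %% 2147483647)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
}
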