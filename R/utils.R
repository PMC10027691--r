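#' Derive independent child seeds from a master seed
#'
#' Child seeds drive per-subject or per-stage RNG streams so that cohorts are
#' reproducible from one master seed while components stay independent.
#' All returned seeds fit in a 32-bit signed integer.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# run a block under a local RNG state; NULL seed leaves the global stream alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, format(min)))
  }
  invisible(x)
}
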