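#' @importFrom rlang abort warn %||%
#' @importFrom stats cor lm optimize predict rbeta rbinom rnorm runif var coef
#' @importFrom utils head modifyList
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded operations never perturb the global stream.
with_seed <- function(seed, code) {
  check_seed(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    abort("`seed` must be a single finite integer.")
  }
  invisible(seed)
}

#' Derive a child seed from a master seed
#'
#' Deterministically maps a (master seed, stream index) pair to a new seed in
#' `[1, 2^31 - 2]`. One master seed can therefore spawn independent, fully
#' reproducible per-stage streams (panel simulation, meiosis, trait noise,
#' subset selection, ...) without coupling them through a single global RNG.
#'
#' @param seed Master integer seed.
#' @param index Non-negative integer stream index.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(42, 1)
child_seed <- function(seed, index) {
  check_seed(seed)
  check_seed(index)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(seed) %% m)
  # two multiplicative mixes keep doubles exact (< 2^53 before each %%)
  s <- (s * 48271 + 1) %% m
  s <- (s + (abs(index) %% m) * 69621) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s %% (m - 1) + 1)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
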