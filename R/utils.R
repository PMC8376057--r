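# Internal helpers: seeding, argument checks.

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' Independent analysis stages (per-habitat bootstrap streams, landscape vs
#' placement randomness) draw from substreams derived deterministically from one
#' master seed, so a single `seed` argument governs a whole run while streams
#' stay decoupled.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  h <- 0
  for (cp in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 131 + cp) %% 2147483629
  }
  as.integer((abs(master) %% 2147483629 * 48271 + h) %% 2147483629)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded stages do not disturb
#' each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# proportions checker shared by composition / availability code
check_proportions <- function(p, name = "proportions", tol = 1e-9) {
  if (any(!is.finite(p))) stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  if (any(p < 0)) stop(sprintf("`%s` contains negative values", name), call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}
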