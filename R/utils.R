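# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage sub-seed from a global seed; keeps results within 32-bit
# integer range and gives distinct, reproducible streams per stage.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483647)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  if (strict_lower && x <= lower) stop("'", name, "' must be > ", lower)
  if (!strict_lower && x < lower) stop("'", name, "' must be >= ", lower)
  if (strict_upper && x >= upper) stop("'", name, "' must be < ", upper)
  if (!strict_upper && x > upper) stop("'", name, "' must be <= ", upper)
  invisible(x)
}
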