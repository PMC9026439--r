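# Internal validation and numeric helpers.

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must lie in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

.assertRange <- function(x, name, lower = -Inf) {
  if (length(x) != 2L || !is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric interval of length 2", name),
         call. = FALSE)
  }
  if (x[1] > x[2]) {
    stop(sprintf("'%s' must have lower <= upper", name), call. = FALSE)
  }
  if (any(x < lower)) {
    stop(sprintf("'%s' must be >= %s", name, format(lower)), call. = FALSE)
  }
  invisible(x)
}

.assertImage <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop(sprintf("'%s' must be at least 3x3", name), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must contain finite intensities in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# round-half-away-from-zero to `digits` decimals (printed-table convention,
# unlike base round()'s round-half-even)
.roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range.
.childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

.clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  attributes(y) <- attributes(x)  # pmin/pmax drop dim when a scalar comes first
  y
}
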