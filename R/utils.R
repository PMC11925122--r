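# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators in the package are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a distinct child seed from a parent seed; keeps values < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Rational approximation p/q of x with q <= max_den (continued fractions).
rational_approx <- function(x, max_den = 4096L) {
  stopifnot(is.finite(x), x > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) < 1e-12) break
    if (b == a) break
    b <- 1 / (b - a)
  }
  c(p = h1, q = k1)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-12) {
    stop(sprintf("%s has (near-)zero length", what), call. = FALSE)
  }
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
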