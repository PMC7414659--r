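# Internal numeric helpers shared across modules.

# Clamp to [-1, 1] before acos/asin; guards against rounding just past 1.
.clamp1 <- function(x) pmin(1, pmax(-1, x))

.norm3 <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < .Machine$double.eps^0.5) {
    abort("cannot normalise a (near-)zero vector", class = "reachkin_error_geometry")
  }
  v / n
}

# Row-wise Euclidean norm of an n x 3 matrix.
.rownorm <- function(m) sqrt(rowSums(m^2))

# Central differences with one-sided ends; x may be a vector or n x k matrix.
# Spacing is 1/fs. Exact for affine signals including at the ends.
.gradient <- function(x, fs) {
  if (is.matrix(x)) {
    return(apply(x, 2L, .gradient, fs = fs))
  }
  n <- length(x)
  if (n < 2L) abort("need at least 2 samples to differentiate",
                    class = "reachkin_error_insufficient_data")
  g <- numeric(n)
  g[1L] <- (x[2L] - x[1L]) * fs
  g[n] <- (x[n] - x[n - 1L]) * fs
  if (n > 2L) g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  g
}

# Deterministic derived seed kept below 2^31 so it stays a valid R integer.
.derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulation calls do not perturb user code.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "reachkin_error_invalid_argument")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name),
          class = "reachkin_error_invalid_argument")
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0", name),
          class = "reachkin_error_invalid_argument")
  }
  invisible(x)
}
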