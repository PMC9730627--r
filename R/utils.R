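# Internal helpers shared across modules: seeded RNG scopes and the
# canonical linear indexing of unordered drug pairs (i < j).

# Run `code` under `set.seed(seed)` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic integer mix of (seed, epoch) for per-epoch resampling.
# Kept strictly below 2^31 (R integers are 32-bit) and well inside the
# exact-double range at every intermediate step.
mix_seed <- function(seed, epoch) {
  s <- as.double(seed %% 100003L)
  e <- as.double(epoch %% 100003L)
  as.integer((s * 10007 + e * 7919 + 12345) %% 2147483647)
}

# Linear index of the unordered pair (i, j), i < j, counting pairs
# column-wise over the strict upper triangle: k = i + (j-1)(j-2)/2.
pair_to_index <- function(i, j) {
  stopifnot(all(i < j))
  i + (j - 1) * (j - 2) / 2
}

# Inverse of pair_to_index().
index_to_pair <- function(k) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

n_pairs <- function(n) n * (n - 1) / 2

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot (Xavier) normal initialization for a weight matrix of the given shape.
glorot_normal <- function(fan_in, fan_out) {
  sd <- sqrt(2 / (fan_in + fan_out))
  matrix(rnorm(fan_in * fan_out, mean = 0, sd = sd), fan_in, fan_out)
}
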