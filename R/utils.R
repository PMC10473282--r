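# Internal helpers shared across modules.

# Coerce any numeric seed (possibly > 2^31 after arithmetic on derived
# seeds) into the valid integer range for set.seed().
as_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer(abs(seed) %% 2147483629)
}

# Derive n reproducible child seeds from a master seed. Used everywhere a
# stage needs its own RNG stream so reruns with the same config are
# bit-identical regardless of evaluation order.
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as_seed(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Strictly-upper-triangle vectorization (diagonal excluded), column-major.
upper_vec <- function(m) m[upper.tri(m)]

# Canonical community labels: relabel to 1..k in order of first appearance,
# so partitions can be compared across label permutations.
canonical_labels <- function(x) {
  f <- match(x, unique(x))
  as.integer(f)
}

# Adjusted Rand index between two partitions (vectors over the same nodes).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
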