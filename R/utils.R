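# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure in (args, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seeds derived from a base seed (kept within 32-bit range).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# All permutations of 1..k as a matrix (k! rows); used for brute-force
# archetype matching.  Intended for k <= 7.
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(X, name = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("%s must be numeric", name)
  if (any(!is.finite(X))) stopf("%s contains non-finite values", name)
  X
}

# Simplex validity of score rows, within tolerance.
check_simplex_rows <- function(A, tol = 1e-4, name = "scores") {
  A <- check_matrix(A, name)
  if (any(A < -tol) || any(abs(rowSums(A) - 1) > tol))
    stopf("%s rows must lie on the probability simplex (tolerance %g)", name, tol)
  A
}
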