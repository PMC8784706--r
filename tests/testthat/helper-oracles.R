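# Independent oracles used across tests; deliberately simple and slow.

# Brute-force Benjamini-Hochberg step-up by its textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive-search version of the greedy correlation pruning rule.
prune_oracle <- function(X, cutoff) {
  keep <- seq_len(ncol(X))
  R <- abs(stats::cor(X)); diag(R) <- 0
  repeat {
    Rk <- R[keep, keep, drop = FALSE]
    if (length(keep) < 2L || max(Rk) <= cutoff) break
    hit <- which(Rk == max(Rk), arr.ind = TRUE)[1L, ]
    i <- keep[hit[1L]]; j <- keep[hit[2L]]
    mi <- mean(R[i, setdiff(keep, i)]); mj <- mean(R[j, setdiff(keep, j)])
    drop_col <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- setdiff(keep, drop_col)
  }
  colnames(X)[keep]
}

# Dense-grid minimizer of ||t - w B||^2 over the probability simplex (k = 3).
simplex_grid_oracle <- function(target, basis, step = 1e-3) {
  w1 <- seq(0, 1, by = step)
  best <- NULL; best_val <- Inf
  for (a in w1) {
    b <- seq(0, 1 - a, by = step)
    cc <- 1 - a - b
    W <- cbind(a, b, cc)
    vals <- rowSums((matrix(target, nrow(W), length(target), byrow = TRUE) -
                       W %*% basis)^2)
    i <- which.min(vals)
    if (vals[i] < best_val) { best_val <- vals[i]; best <- W[i, ] }
  }
  best
}

# Small standard synthetic cohort reused by several tests.
small_cohort <- function(n = 250, seed = 11, ...) {
  generate_cohort(cohort_config(n, seed = seed, ...))
}
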