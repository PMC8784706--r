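#' Simplex-constrained least squares for a set of target rows
#'
#' Solves, independently for every row \eqn{t} of \code{targets},
#' \deqn{\min_w \|t - w B\|^2 \quad s.t. \quad w \ge 0,\ \sum_j w_j = 1,}
#' where \eqn{B} is the basis matrix.  The equality constraint is enforced by
#' non-negative least squares on the system augmented with a heavily weighted
#' sum-to-one row; the augmentation weight is \code{M = weight_factor *
#' max(abs(basis))}.  This is the inner solver of the archetypal-analysis
#' alternating scheme.
#'
#' @param targets numeric matrix (rows are targets) or a single vector.
#' @param basis numeric matrix whose rows span the candidate hull; must have
#'   the same number of columns as \code{targets}.
#' @param weight_factor scale factor for the sum-to-one augmentation row.
#' @return matrix of simplex weights, one row per target row.
#' @export
solve_simplex_weights <- function(targets, basis, weight_factor = 200) {
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1L)
  targets <- check_matrix(targets, "targets")
  basis <- check_matrix(basis, "basis")
  if (nrow(basis) < 1L) stopf("basis must have at least one row")
  if (ncol(targets) != ncol(basis))
    stopf("targets have %d columns but basis has %d", ncol(targets), ncol(basis))
  M <- weight_factor * max(abs(basis), 1e-12)
  .simplex_ls_rows_cpp(targets, basis, M)
}

# Furthest-point initialization: first row drawn at random (seeded), each
# subsequent row maximizes the minimal distance to those already chosen.
# Reduces the rate of degenerate restarts compared to uniform sampling.
init_rows_furthest <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[idx[1L], ])^2)
    for (j in 2L:k) {
      idx[j] <- which.max(d2)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[j], ])^2))
    }
  }
  idx
}

# Tukey bisquare weights from residual norms; tuning constant 6 * median
# norm, floored by half the median centroid distance (scale_floor).  The
# floor keeps near-noiseless data from being progressively down-weighted to
# a collapsed interior solution, while residuals far beyond the bulk spread
# (gross outliers) still receive weight zero.
bisquare_weights <- function(rnorm2, scale_floor) {
  r <- sqrt(rnorm2)
  cc <- 6 * max(stats::median(r), scale_floor)
  if (cc <= 0) return(rep(1, length(r)))
  w <- (1 - (r / cc)^2)^2
  w[r >= cc] <- 0
  w
}

als_archetypes <- function(X, k, tol, max_iter, seed, robust,
                           weight_factor = 200) {
  X <- check_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (k < 1L) stopf("k must be >= 1")
  if (k > n) stopf("k = %d exceeds the number of observations (%d)", k, n)

  a_step <- function(Z) solve_simplex_weights(X, Z, weight_factor)
  rss_of <- function(A, Z) sum((X - A %*% Z)^2)

  # centroid-distance scale: reference for the bisquare floor and for
  # keeping gross outliers out of the furthest-point seeding
  r0 <- sqrt(rowSums(sweep(X, 2L, colMeans(X))^2))
  scale_floor <- stats::median(r0) / 2

  with_seed(seed, {
    if (robust) {
      w0 <- bisquare_weights(r0^2, scale_floor)
      ok <- which(w0 >= 0.5)
      if (length(ok) < k) ok <- seq_len(n)
      Z <- X[ok[init_rows_furthest(X[ok, , drop = FALSE], k)], ,
             drop = FALSE]
    } else {
      Z <- X[init_rows_furthest(X, k), , drop = FALSE]
    }
    A <- a_step(Z)
    B <- NULL
    w <- rep(1, n)
    rss <- rss_of(A, Z)
    trace <- rss
    converged <- FALSE
    reinit_events <- 0L
    iter <- 0L

    while (iter < max_iter) {
      iter <- iter + 1L
      if (robust) {
        res2 <- rowSums((X - A %*% Z)^2)
        w <- bisquare_weights(res2, scale_floor)
        if (all(w == 0)) w <- rep(1, n)
      }
      # weighted unconstrained archetype update, then projection onto the
      # convex hull of the data rows (Z = B X keeps archetypes in the hull)
      AtWA <- crossprod(A, A * w)
      Zhat <- tryCatch(
        solve(AtWA + diag(1e-10 * max(diag(AtWA), 1), k), crossprod(A, X * w)),
        error = function(e) Z)
      B_new <- solve_simplex_weights(Zhat, X, weight_factor)
      Z_new <- B_new %*% X
      A_new <- a_step(Z_new)

      # re-seed archetypes that no observation uses
      unused <- which(apply(A_new, 2L, max) < 1e-6)
      reinit <- length(unused) > 0L
      if (reinit) {
        reinit_events <- reinit_events + length(unused)
        res2 <- rowSums((X - A_new %*% Z_new)^2)
        for (j in unused) {
          i_worst <- which.max(res2)
          Z_new[j, ] <- X[i_worst, ]
          B_new[j, ] <- 0; B_new[j, i_worst] <- 1
          res2[i_worst] <- 0
        }
        A_new <- a_step(Z_new)
      }

      rss_new <- rss_of(A_new, Z_new)
      if (!robust && !reinit && rss_new > rss + 1e-8 * max(rss, 1)) {
        converged <- TRUE  # projection step cannot improve further
        break
      }
      rel <- abs(rss - rss_new) / max(rss, .Machine$double.eps)
      A <- A_new; B <- B_new; Z <- Z_new; rss <- rss_new
      trace <- c(trace, rss)
      if (rel < tol || rss < 1e-12 * sum(X^2)) { converged <- TRUE; break }
    }

    if (is.null(B)) B <- solve_simplex_weights(Z, X, weight_factor)
    colnames(Z) <- colnames(X)
    structure(list(
      archetypes = Z, scores = A, mixers = B, rss = rss, k = k,
      robust_weights = w, iterations = iter, converged = converged,
      rss_trace = trace, reinit_events = reinit_events, seed = seed,
      robust = robust), class = "archetype_model")
  })
}

#' Fit an archetypal-analysis model by alternating constrained least squares
#'
#' Decomposes a data matrix \eqn{X \approx A Z}, with per-observation scores
#' \eqn{A} on the probability simplex and archetypes \eqn{Z = B X} constrained
#' to the convex hull of the observations (\eqn{B} rows also on the simplex).
#' Iterates a score step, an unconstrained archetype update and a hull
#' projection until the relative change in residual sum of squares falls
#' below \code{tol}.  The RSS trace is non-increasing: an iteration that
#' would increase the RSS terminates the fit at the previous iterate.
#'
#' @param X numeric matrix, observations in rows.
#' @param k number of archetypes (1 \eqn{\le} k \eqn{\le} nrow(X)).
#' @param tol relative RSS change declaring convergence.
#' @param max_iter maximum number of alternating iterations.
#' @param seed integer seed for the furthest-point initialization.
#' @return an object of class \code{archetype_model}: archetypes \code{Z}
#'   (k x m), simplex scores (n x k), mixers \code{B} (k x n), \code{rss},
#'   iteration count, convergence flag and the RSS trace.
#' @seealso [fit_robust_archetypes()], [best_of_restarts()], [project_scores()]
#' @export
fit_archetypes <- function(X, k, tol = 1e-6, max_iter = 200, seed = NULL) {
  als_archetypes(X, k, tol, max_iter, seed, robust = FALSE)
}

#' Robust archetypal analysis via iteratively reweighted least squares
#'
#' As [fit_archetypes()], but each outer iteration recomputes per-observation
#' Tukey bisquare weights from the residual norms (tuning constant six times
#' the median residual norm, floored at half the median centroid distance so
#' that clean data are not down-weighted) and solves the archetype update by
#' weighted least squares, so that gross outliers do not drag the
#' archetypes.  Observations with residual norm beyond the tuning constant
#' get weight 0, and rows flagged as outlying against the centroid spread
#' are excluded from the furthest-point seeding.
#'
#' @inheritParams fit_archetypes
#' @return an \code{archetype_model}; \code{robust_weights} holds the final
#'   per-observation weights in \eqn{[0, 1]}.
#' @export
fit_robust_archetypes <- function(X, k, tol = 1e-6, max_iter = 200, seed = NULL) {
  als_archetypes(X, k, tol, max_iter, seed, robust = TRUE)
}

#' Best archetypal model over random restarts
#'
#' Runs the (robust) archetype fit from \code{n_restarts} seeded random
#' initializations and returns the model with the smallest residual sum of
#' squares.  Per-restart seeds are derived deterministically from \code{seed},
#' so the result is reproducible.
#'
#' @inheritParams fit_archetypes
#' @param n_restarts number of random restarts.
#' @param robust use the robust (bisquare-reweighted) variant; default TRUE.
#' @return the \code{archetype_model} with minimal RSS across restarts.  If no
#'   restart converged, the best model is returned with
#'   \code{converged = FALSE} and a warning.
#' @export
best_of_restarts <- function(X, k, n_restarts = 100, seed = NULL,
                             robust = TRUE, tol = 1e-6, max_iter = 200) {
  if (n_restarts < 1L) stopf("n_restarts must be >= 1")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- als_archetypes(X, k, tol, max_iter, seeds[r], robust = robust)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (!best$converged)
    warning("no restart converged; returning the lowest-RSS model")
  best$n_restarts <- n_restarts
  best$base_seed <- seed
  best
}

#' Project new observations onto a fitted archetype basis
#'
#' Solves the score step only, with the archetypes held fixed, returning
#' simplex score rows for \code{X_new}.  Used to score follow-up visits
#' against a baseline model.
#'
#' @param model an \code{archetype_model}.
#' @param X_new matrix with the same columns as the training data.
#' @return matrix of simplex scores (rows sum to 1).
#' @export
project_scores <- function(model, X_new) {
  stopifnot(inherits(model, "archetype_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1L)
  if (ncol(X_new) != ncol(model$archetypes))
    stopf("X_new has %d columns; model expects %d",
          ncol(X_new), ncol(model$archetypes))
  solve_simplex_weights(X_new, model$archetypes)
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("Archetypal analysis model (%s)\n",
              if (isTRUE(x$robust)) "robust" else "plain"))
  cat(sprintf("  k = %d archetypes over %d variables, %d observations\n",
              x$k, ncol(x$archetypes), nrow(x$scores)))
  cat(sprintf("  RSS = %.6g after %d iterations (%s)\n", x$rss, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
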