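#' RSS scree over a range of archetype numbers
#'
#' Fits the best-of-restarts archetype model for every k in \code{k_range}
#' and collects the minimized residual sum of squares, for scree-plot based
#' choice of the number of archetypes.
#'
#' @param X numeric data matrix.
#' @param k_range integer vector of candidate archetype numbers.
#' @param n_restarts restarts per k.
#' @param seed integer seed (per-k seeds derived deterministically).
#' @param ... passed to [best_of_restarts()].
#' @return data.frame of class \code{scree_result}: \code{k}, \code{rss}.
#' @export
scree <- function(X, k_range = 1:10, n_restarts = 100, seed = 1, ...) {
  if (length(k_range) == 0L) stopf("k_range must be non-empty")
  if (max(k_range) > nrow(X)) stopf("max(k_range) exceeds the number of rows")
  seeds <- derive_seeds(seed, length(k_range))
  rss <- vapply(seq_along(k_range), function(i)
    best_of_restarts(X, k_range[i], n_restarts, seeds[i], ...)$rss, 1.0)
  structure(data.frame(k = k_range, rss = rss),
            class = c("scree_result", "data.frame"))
}

cosine_similarity_matrix <- function(Za, Zb) {
  na <- sqrt(rowSums(Za^2)); nb <- sqrt(rowSums(Zb^2))
  (Za %*% t(Zb)) / (pmax(na, 1e-300) %o% pmax(nb, 1e-300))
}

#' Match archetypes between two fits by cosine similarity
#'
#' Finds the one-to-one assignment of \code{Z_new} rows to \code{Z_ref} rows
#' maximizing the total cosine similarity, by exhaustive search over
#' permutations (k <= 7).  When the fits used different column sets, supply
#' \code{shared_columns} to restrict the comparison.
#'
#' @param Z_ref,Z_new k x m archetype matrices (same k; columns matched by
#'   name when \code{shared_columns} is given).
#' @param shared_columns optional column names used for the comparison.
#' @return list: \code{permutation} (index into Z_new rows for each Z_ref
#'   row), \code{similarity} per matched pair, \code{total}.
#' @export
match_archetypes <- function(Z_ref, Z_new, shared_columns = NULL) {
  if (nrow(Z_ref) != nrow(Z_new)) stopf("archetype counts differ")
  if (!is.null(shared_columns)) {
    Z_ref <- Z_ref[, shared_columns, drop = FALSE]
    Z_new <- Z_new[, shared_columns, drop = FALSE]
  }
  if (ncol(Z_ref) != ncol(Z_new)) stopf("column sets differ")
  k <- nrow(Z_ref)
  if (k > 7L) stopf("exhaustive matching supports k <= 7")
  S <- cosine_similarity_matrix(Z_ref, Z_new)
  perms <- permutations_of(k)
  totals <- apply(perms, 1L, function(p) sum(S[cbind(seq_len(k), p)]))
  best <- perms[which.max(totals), ]
  list(permutation = best, similarity = S[cbind(seq_len(k), best)],
       total = max(totals))
}

#' Threshold-based archetype membership labels
#'
#' Labels each subject by its argmax archetype when the maximal score
#' strictly exceeds \code{threshold}, else by the sentinel \code{"mixed"}.
#' At threshold 0 every subject receives its argmax archetype.
#'
#' @param scores simplex score rows (validated to tolerance 1e-4).
#' @param threshold membership cutoff in [0, 1].
#' @return character vector of labels.
#' @export
assign_labels <- function(scores, threshold) {
  scores <- check_simplex_rows(scores)
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  arch_names <- colnames(scores)
  if (is.null(arch_names)) arch_names <- LETTERS[seq_len(ncol(scores))]
  top <- max.col(scores, ties.method = "first")
  labs <- arch_names[top]
  labs[scores[cbind(seq_len(nrow(scores)), top)] <= threshold] <- "mixed"
  labs
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same subjects: 1 for identical partitions, expectation 0 under
#' independent random labelings.  When both partitions are trivial (the
#' pair-counting denominator vanishes) the value is 1 if the partitions are
#' equal and 0 otherwise.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return adjusted Rand index in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stopf("label lengths differ")
  n <- length(labels_a)
  if (n < 2L) stopf("need at least 2 subjects")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (abs(denom) < .Machine$double.eps) {
    # both partitions trivial: equal partitions get 1, unequal 0
    return(as.numeric(all(outer(labels_a, labels_a, "==") ==
                            outer(labels_b, labels_b, "=="))))
  }
  (sum_ij - expected) / denom
}

#' Archetype stability under randomized subsampling
#'
#' Fits a reference model on the full data, then repeatedly refits on
#' random subsamples (without replacement), matches the replicate archetypes
#' to the reference by cosine similarity, labels subjects by thresholded
#' membership, and scores the agreement with the reference labels on the
#' subsampled subjects via the adjusted Rand index — across a ladder of
#' membership thresholds.  Subjects below threshold form one "mixed" class
#' inside the ARI by default; \code{mixed = "exclude"} drops them instead.
#'
#' @param X data matrix.
#' @param k number of archetypes.
#' @param fraction subsample fraction in (0, 1) (default 0.9).
#' @param replicates number of subsampling replicates (default 100).
#' @param thresholds membership cutoffs (default 0 to 1 by 0.05).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param ref_restarts restarts for the reference fit.
#' @param replicate_restarts restarts per replicate refit.
#' @param mixed \code{"pool"} or \code{"exclude"}.
#' @param reference optionally a pre-fitted reference \code{archetype_model}.
#' @return list of class \code{stability_result}: \code{ari} data.frame
#'   (threshold, replicate, ari), \code{median_ari} per threshold,
#'   \code{reference} model, and the protocol settings.
#' @export
stability_by_subsampling <- function(X, k, fraction = 0.9, replicates = 100,
                                     thresholds = seq(0, 1, by = 0.05),
                                     seed = 1, ref_restarts = 20,
                                     replicate_restarts = 5,
                                     mixed = c("pool", "exclude"),
                                     reference = NULL) {
  mixed <- match.arg(mixed)
  X <- check_matrix(X)
  if (!(fraction > 0 && fraction < 1)) stopf("fraction must be in (0, 1)")
  if (replicates < 1L) stopf("replicates must be >= 1")
  n <- nrow(X)
  n_sub <- floor(fraction * n)
  if (n_sub < k) stopf("subsample smaller than k")

  if (is.null(reference))
    reference <- best_of_restarts(X, k, ref_restarts, seed)
  ref_scores <- reference$scores
  colnames(ref_scores) <- rownames(reference$archetypes) %||%
    LETTERS[seq_len(k)]

  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    seed_r <- seed + r
    idx <- with_seed(seed_r, sample.int(n, n_sub))
    fit_r <- best_of_restarts(X[idx, , drop = FALSE], k, replicate_restarts,
                              seed_r)
    mm <- match_archetypes(reference$archetypes, fit_r$archetypes)
    scores_r <- fit_r$scores[, mm$permutation, drop = FALSE]
    colnames(scores_r) <- colnames(ref_scores)
    ari <- vapply(thresholds, function(th) {
      la <- assign_labels(ref_scores[idx, , drop = FALSE], th)
      lb <- assign_labels(scores_r, th)
      if (mixed == "exclude") {
        keep <- la != "mixed" & lb != "mixed"
        if (sum(keep) < 2L) return(NA_real_)
        la <- la[keep]; lb <- lb[keep]
      }
      adjusted_rand_index(la, lb)
    }, 1.0)
    out[[r]] <- data.frame(threshold = thresholds, replicate = r, ari = ari)
  }
  ari_df <- do.call(rbind, out)
  med <- stats::aggregate(ari ~ threshold, ari_df, stats::median,
                          na.action = stats::na.omit)
  structure(list(ari = ari_df,
                 median_ari = stats::setNames(med$ari, med$threshold),
                 k = k, fraction = fraction, replicates = replicates,
                 thresholds = thresholds, reference = reference, seed = seed),
            class = "stability_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Search for a minimal phenotype set preserving the archetypes
#'
#' Sweeps a descending ladder of correlation cutoffs; at each cutoff the
#' phenotype set is pruned ([prune_by_correlation()]), the archetype model
#' is refitted on the retained columns, and the refitted archetypes are
#' matched to the full-model archetypes on the shared columns.  Returns the
#' smallest retained set (the lowest cutoff) whose matched cosine
#' similarities all exceed \code{similarity_threshold}; if no cutoff
#' qualifies, the best attempt is returned with \code{satisfied = FALSE}.
#'
#' @param X data matrix with column names.
#' @param cutoffs descending correlation cutoffs in (0, 1) (default 0.8 to
#'   0.2 by 0.1).
#' @param k number of archetypes.
#' @param similarity_threshold minimum cosine similarity (default 0.8).
#' @param seed integer seed.
#' @param n_restarts restarts per refit.
#' @return list: \code{cutoff}, \code{retained}, \code{similarities},
#'   \code{satisfied}, and the per-cutoff sweep table.
#' @export
find_minimal_parameter_set <- function(X, cutoffs = seq(0.8, 0.2, by = -0.1),
                                       k = 4, similarity_threshold = 0.8,
                                       seed = 1, n_restarts = 20) {
  if (any(diff(cutoffs) >= 0) || any(cutoffs <= 0 | cutoffs >= 1))
    stopf("cutoffs must be strictly descending within (0, 1)")
  X <- check_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  full <- best_of_restarts(X, k, n_restarts, seed)
  sweep_rows <- list()
  chosen <- NULL
  best_attempt <- NULL
  for (cc in cutoffs) {
    retained <- prune_by_correlation(X, cc)
    if (length(retained) < 2L) next
    fit <- best_of_restarts(X[, retained, drop = FALSE], k, n_restarts, seed)
    mm <- match_archetypes(full$archetypes, fit$archetypes,
                           shared_columns = retained)
    ok <- all(mm$similarity > similarity_threshold)
    sweep_rows[[length(sweep_rows) + 1L]] <-
      data.frame(cutoff = cc, n_retained = length(retained),
                 min_similarity = min(mm$similarity), satisfied = ok)
    cand <- list(cutoff = cc, retained = retained,
                 similarities = mm$similarity, satisfied = ok)
    if (ok) chosen <- cand
    if (is.null(best_attempt) ||
        min(mm$similarity) > min(best_attempt$similarities))
      best_attempt <- cand
  }
  res <- chosen %||% best_attempt
  if (is.null(res)) stopf("no cutoff produced a usable pruned set")
  res$sweep <- do.call(rbind, sweep_rows)
  res$full_model <- full
  res
}
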