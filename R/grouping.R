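#' Extreme-archetype group assignment
#'
#' Labels each subject by the archetype whose score strictly exceeds
#' \code{threshold}; all others get \code{"MIX"}.  Because the scores sum
#' to 1, at most one archetype can exceed any threshold above 0.5, so the
#' label is unique at the default 0.6 cutoff.  For thresholds at or below
#' 0.5 a warning is emitted and ties break on the first maximum.
#'
#' @param scores simplex score rows.
#' @param threshold strict membership cutoff (default 0.6).
#' @return character vector with levels among the archetype names and
#'   \code{"MIX"}.
#' @export
assign_extreme_groups <- function(scores, threshold = 0.6) {
  scores <- check_simplex_rows(scores)
  if (threshold <= 0.5)
    warning("threshold <= 0.5 does not guarantee a unique extreme archetype; ",
            "using the first maximum")
  arch_names <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  top <- max.col(scores, ties.method = "first")
  labs <- arch_names[top]
  labs[scores[cbind(seq_len(nrow(scores)), top)] <= threshold] <- "MIX"
  labs
}

#' Mixed-etiology (primary/secondary archetype) group assignment
#'
#' Forms the ordered pair of each subject's highest and second-highest
#' scoring archetypes (e.g. \code{"AB"}), with ties broken by the fixed
#' archetype order, and classifies dominance: how many scores reach the
#' \code{dominance} cutoff (0 none_dominating, 1 single_dominating,
#' 2 two_dominating).  With k = 4 archetypes the label space has exactly
#' 12 ordered pairs.  Subjects whose top score exceeds
#' \code{extreme_threshold} can optionally be folded into their single
#' letter with category \code{"extreme"}.
#'
#' @param scores simplex score rows.
#' @param dominance dominance cutoff (default 0.4, inclusive).
#' @param extreme_threshold when non-NULL, scores strictly above it yield
#'   the single-letter label and category \code{"extreme"}.
#' @return data.frame: \code{mixed_label}, \code{dominance_category}.
#' @export
assign_mixed_groups <- function(scores, dominance = 0.4,
                                extreme_threshold = NULL) {
  scores <- check_simplex_rows(scores)
  arch_names <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  n <- nrow(scores)
  lab <- character(n)
  cat_ <- character(n)
  for (i in seq_len(n)) {
    # order by decreasing score with the fixed archetype order breaking ties
    ord <- order(-scores[i, ], seq_along(arch_names))
    n_dom <- sum(scores[i, ] >= dominance)
    if (!is.null(extreme_threshold) &&
        scores[i, ord[1L]] > extreme_threshold) {
      lab[i] <- arch_names[ord[1L]]
      cat_[i] <- "extreme"
    } else {
      lab[i] <- paste0(arch_names[ord[1L]], arch_names[ord[2L]])
      cat_[i] <- c("none_dominating", "single_dominating",
                   "two_dominating")[min(n_dom, 2L) + 1L]
    }
  }
  data.frame(mixed_label = lab, dominance_category = cat_)
}

#' Group transition flows between consecutive visits
#'
#' Counts, for each pair of consecutive visits, how many subjects moved
#' from each group to each group (subjects present at both visits).  Flows
#' below \code{min_count} are retained but flagged, mirroring the display
#' convention of showing only trajectories followed by at least 5
#' participants.
#'
#' @param assignments data.frame with columns \code{subject_id},
#'   \code{visit_month}, \code{group}.
#' @param min_count display threshold (default 5).
#' @return data.frame: \code{from_month}, \code{to_month}, \code{from},
#'   \code{to}, \code{count}, \code{displayed}.
#' @export
transition_flows <- function(assignments, min_count = 5) {
  need <- c("subject_id", "visit_month", "group")
  if (!all(need %in% names(assignments)))
    stopf("assignments needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(assignments[c("subject_id", "visit_month")]))
    stopf("duplicate (subject, visit) rows")
  months <- sort(unique(assignments$visit_month))
  if (length(months) < 2L) stopf("need at least two visits")
  rows <- list()
  for (i in seq_len(length(months) - 1L)) {
    a <- assignments[assignments$visit_month == months[i], ]
    b <- assignments[assignments$visit_month == months[i + 1L], ]
    common <- intersect(a$subject_id, b$subject_id)
    if (!length(common)) next
    ga <- a$group[match(common, a$subject_id)]
    gb <- b$group[match(common, b$subject_id)]
    tab <- as.data.frame(table(from = ga, to = gb),
                         responseName = "count",
                         stringsAsFactors = FALSE)
    tab <- tab[tab$count > 0, , drop = FALSE]
    tab$from_month <- months[i]
    tab$to_month <- months[i + 1L]
    rows[[length(rows) + 1L]] <- tab
  }
  flows <- do.call(rbind, rows)
  flows$displayed <- flows$count >= min_count
  flows[c("from_month", "to_month", "from", "to", "count", "displayed")]
}

#' Pairwise correlations of archetype scores across visits
#'
#' For every archetype and every pair of visits, the Pearson correlation of
#' that archetype's scores over the subjects present at both visits.
#'
#' @param scores_by_visit named list of score matrices with subject ids as
#'   row names (one element per visit).
#' @return data.frame: \code{archetype}, \code{visit_a}, \code{visit_b},
#'   \code{r}, \code{n}.
#' @export
cross_visit_score_correlations <- function(scores_by_visit) {
  if (length(scores_by_visit) < 2L) stopf("need at least two visits")
  visits <- names(scores_by_visit) %||%
    as.character(seq_along(scores_by_visit))
  rows <- list()
  for (i in seq_len(length(scores_by_visit) - 1L)) {
    for (j in (i + 1L):length(scores_by_visit)) {
      Sa <- scores_by_visit[[i]]; Sb <- scores_by_visit[[j]]
      common <- intersect(rownames(Sa), rownames(Sb))
      if (length(common) < 3L)
        stopf("fewer than 3 overlapping subjects between visits %s and %s",
              visits[i], visits[j])
      arch <- colnames(Sa) %||% LETTERS[seq_len(ncol(Sa))]
      for (a in seq_len(ncol(Sa))) {
        rows[[length(rows) + 1L]] <- data.frame(
          archetype = arch[a], visit_a = visits[i], visit_b = visits[j],
          r = stats::cor(Sa[common, a], Sb[common, a]),
          n = length(common))
      }
    }
  }
  do.call(rbind, rows)
}
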