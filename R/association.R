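#' Linear association of archetype scores with a continuous outcome
#'
#' One OLS regression per archetype score (marginal models — the k scores
#' sum to 1 and are collinear, so a joint model is refused by design).
#'
#' @param scores simplex score matrix.
#' @param outcome numeric outcome vector, same subjects.
#' @param joint must remain FALSE; requesting a joint model of all scores is
#'   refused because the simplex constraint makes it rank deficient.
#' @return data.frame: \code{archetype}, \code{estimate}, \code{se},
#'   \code{p}, \code{n}.
#' @export
score_phenotype_association <- function(scores, outcome, joint = FALSE) {
  if (isTRUE(joint))
    stopf(paste("archetype scores sum to one, so a joint model is rank",
                "deficient; marginal per-score models are fitted instead"))
  scores <- check_simplex_rows(scores)
  if (length(outcome) != nrow(scores)) stopf("length mismatch")
  if (stats::sd(outcome) == 0) stopf("outcome has zero variance")
  arch <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  rows <- lapply(seq_along(arch), function(a) {
    if (stats::sd(scores[, a]) == 0)
      return(data.frame(archetype = arch[a], estimate = NA_real_,
                        se = NA_real_, p = NA_real_, n = length(outcome),
                        row.names = NULL))
    m <- summary(stats::lm(outcome ~ scores[, a]))
    co <- m$coefficients[2L, ]
    data.frame(archetype = arch[a], estimate = co[1L], se = co[2L],
               p = co[4L], n = length(outcome), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Nonparametric tests across extreme archetype groups
#'
#' Kruskal-Wallis test of the outcome across all groups, plus a two-sided
#' Mann-Whitney U test of each group against all remaining subjects, with
#' the effect direction reported as the rank-biserial correlation
#' (positive when the group tends to higher outcome values).
#'
#' @param labels group labels (e.g. A/B/C/D/MIX).
#' @param outcome numeric outcome.
#' @return list: \code{kruskal_p}, and data.frame \code{groups} (group, n,
#'   mann_whitney_p, rank_biserial).
#' @export
extreme_group_tests <- function(labels, outcome) {
  if (length(labels) != length(outcome)) stopf("length mismatch")
  tab <- table(labels)
  if (sum(tab > 0) < 2L) stopf("need at least two non-empty groups")
  kw <- stats::kruskal.test(outcome, factor(labels))
  rows <- list()
  for (g in names(tab)) {
    ing <- labels == g
    if (sum(ing) < 2L) {
      warning(sprintf("group '%s' has < 2 subjects; skipped", g))
      next
    }
    wt <- stats::wilcox.test(outcome[ing], outcome[!ing], exact = FALSE)
    n1 <- sum(ing); n2 <- sum(!ing)
    rb <- 2 * wt$statistic / (n1 * n2) - 1  # rank-biserial from U
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = n1, mann_whitney_p = wt$p.value,
      rank_biserial = unname(rb), row.names = NULL)
  }
  list(kruskal_p = kw$p.value, groups = do.call(rbind, rows))
}

#' Odds of medication use by archetype score
#'
#' Logistic regression of a binary medication status on each archetype
#' score separately, reporting the odds ratio per unit score with a 95%
#' Wald interval.  Complete or quasi-complete separation is detected from
#' the divergence of the coefficient and handled by refitting with a small
#' ridge penalty on the score coefficient (flagged in the output).
#'
#' @param scores simplex score matrix.
#' @param status binary 0/1 vector.
#' @return data.frame: \code{archetype}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{penalized}.
#' @export
medication_odds <- function(scores, status) {
  scores <- check_simplex_rows(scores)
  status <- as.numeric(status)
  if (!all(status %in% c(0, 1))) stopf("status must be binary")
  if (length(unique(status)) < 2L) stopf("status must contain both classes")
  arch <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  rows <- lapply(seq_along(arch), function(a) {
    x <- scores[, a]
    m <- suppressWarnings(stats::glm(status ~ x, family = stats::binomial()))
    co <- summary(m)$coefficients
    penalized <- FALSE
    if (!m$converged || abs(co[2L, 1L]) > 15) {
      # ridge-penalized IRLS fallback for separation
      co <- ridge_logistic(x, status, lambda = 1e-2)
      penalized <- TRUE
    }
    est <- co[2L, 1L]; se <- co[2L, 2L]
    data.frame(archetype = arch[a], or = exp(est),
               ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
               p = 2 * stats::pnorm(-abs(est / se)), penalized = penalized,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# Minimal ridge-penalized logistic regression (intercept unpenalized).
ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y)), 0)
  Pen <- diag(c(0, lambda))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + Pen
    g <- crossprod(X, y - p) - Pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  cbind(Estimate = beta, `Std. Error` = se)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' preserving the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values)))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Omics association screen with per-dataset FDR control
#'
#' Regresses every feature on every archetype score (marginal OLS) and
#' adjusts the p-values by Benjamini-Hochberg within the screen.  The
#' metformin sensitivity modes either restrict to untreated subjects
#' (\code{"subset"}) or add metformin status as a covariate
#' (\code{"covariate"}).  Constant features are skipped with a message.
#' The per-feature regressions are computed in closed form from
#' correlations for speed.
#'
#' @param scores simplex score matrix.
#' @param features subjects x features numeric matrix.
#' @param stratify_metformin \code{"none"}, \code{"subset"} or
#'   \code{"covariate"}.
#' @param metformin binary per-subject metformin status (required unless
#'   mode is \code{"none"}).
#' @return data.frame of class \code{omics_screen}: \code{feature},
#'   \code{archetype}, \code{estimate}, \code{se}, \code{p}, \code{q},
#'   \code{n}, \code{mode}.
#' @export
omics_screen <- function(scores, features,
                         stratify_metformin = c("none", "subset", "covariate"),
                         metformin = NULL) {
  mode <- match.arg(stratify_metformin)
  scores <- check_simplex_rows(scores)
  features <- check_matrix(features, "features")
  if (nrow(features) != nrow(scores)) stopf("subject counts differ")
  if (mode != "none" && is.null(metformin))
    stopf("metformin status required for mode '%s'", mode)
  if (mode == "subset") {
    keep <- metformin == 0
    scores <- scores[keep, , drop = FALSE]
    features <- features[keep, , drop = FALSE]
  }
  const <- apply(features, 2L, stats::sd) == 0
  if (any(const)) {
    message(sprintf("skipping %d constant feature(s)", sum(const)))
    features <- features[, !const, drop = FALSE]
  }
  arch <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  feat_names <- colnames(features) %||% paste0("feat_", seq_len(ncol(features)))
  n <- nrow(features)
  rows <- list()
  for (a in seq_along(arch)) {
    x <- scores[, a]
    yy <- features
    if (mode == "covariate") {
      # residualize both sides on metformin status, then simple regression
      x <- stats::resid(stats::lm(x ~ metformin))
      yy <- qr.resid(qr(cbind(1, metformin)), yy)
    }
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    beta <- drop(crossprod(yy, xc)) / sxx
    tot_ss <- colSums(yy^2) - nrow(yy) * colMeans(yy)^2
    fit_ss <- tot_ss - beta^2 * sxx
    df <- n - 2L - (mode == "covariate")
    se <- sqrt(pmax(fit_ss, 0) / df / sxx)
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    rows[[a]] <- data.frame(feature = feat_names, archetype = arch[a],
                            estimate = beta, se = se, p = p, n = n,
                            mode = mode, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  class(out) <- c("omics_screen", "data.frame")
  out
}

#' Weighted genetic risk score
#'
#' Per-subject weighted sum of risk-allele dosages, over all SNPs or over
#' one mechanism partition (IS1, IS2, IA, BMI, LIPID, MIX).
#'
#' @param dosages subjects x SNPs matrix of 0/1/2 dosages, SNP column names.
#' @param weights data.frame with \code{snp}, \code{weight} and optionally
#'   \code{partition}.
#' @param partition optional partition label selecting a weight subset.
#' @return named numeric vector of scores.
#' @export
compute_grs <- function(dosages, weights, partition = NULL) {
  dosages <- check_matrix(dosages, "dosages")
  w <- weights
  if (!is.null(partition)) {
    if (!"partition" %in% names(w)) stopf("weights carry no partition labels")
    w <- w[w$partition == partition, , drop = FALSE]
    if (nrow(w) == 0L) stopf("no SNPs in partition '%s'", partition)
  }
  missing_snp <- setdiff(w$snp, colnames(dosages))
  if (length(missing_snp))
    stopf("SNPs absent from dosages: %s", paste(missing_snp, collapse = ", "))
  drop(dosages[, w$snp, drop = FALSE] %*% w$weight)
}

#' All partitioned genetic risk scores at once
#'
#' @param dosages,weights as in [compute_grs()].
#' @return data.frame with the overall score (\code{T2D}) and one column per
#'   partition present in \code{weights}.
#' @export
grs_table <- function(dosages, weights) {
  out <- data.frame(T2D = compute_grs(dosages, weights))
  for (pp in sort(unique(weights$partition)))
    out[[pp]] <- compute_grs(dosages, weights, pp)
  rownames(out) <- rownames(dosages)
  out
}
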