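#' Effective medication covariates at a visit
#'
#' A medication contributes at a visit only if started at least 30 days
#' before the visit (and not stopped).  Metformin dose is its fraction of
#' the maximal dose (3 g); other oral agents contribute the sum of their
#' dose fractions; insulin contributes an indicator.
#'
#' @param medications data.frame with \code{drug_class} (one of
#'   \code{metformin}, \code{other_oral}, \code{insulin}),
#'   \code{dose_fraction}, \code{start_day}, \code{stop_day} (may be Inf),
#'   optionally \code{drug} for distinguishing same-class drugs.
#' @param month visit time in months from baseline (30.4375 days/month).
#' @param lag_days effectiveness lag (default 30).
#' @return named numeric vector: \code{metformin_dose}, \code{other_dose},
#'   \code{insulin}.
#' @export
effective_dose <- function(medications, month, lag_days = 30) {
  out <- c(metformin_dose = 0, other_dose = 0, insulin = 0)
  if (is.null(medications) || nrow(medications) == 0L) return(out)
  day <- month * 30.4375
  # reject overlapping duplicates of the same drug
  key <- if ("drug" %in% names(medications)) medications$drug else
    ifelse(medications$drug_class == "other_oral",
           paste0("other_", seq_len(nrow(medications))),
           medications$drug_class)
  for (kk in unique(key)) {
    rows <- medications[key == kk, , drop = FALSE]
    if (nrow(rows) > 1L) {
      ord <- order(rows$start_day)
      starts <- rows$start_day[ord]; stops <- rows$stop_day[ord]
      if (any(starts[-1L] <= utils::head(stops, -1L)))
        stopf("overlapping medication records for '%s'", kk)
    }
  }
  active <- medications$start_day <= day - lag_days &
    (is.infinite(medications$stop_day) | medications$stop_day >= day)
  act <- medications[active, , drop = FALSE]
  if (nrow(act)) {
    out["metformin_dose"] <-
      sum(act$dose_fraction[act$drug_class == "metformin"])
    out["other_dose"] <- sum(act$dose_fraction[act$drug_class == "other_oral"])
    out["insulin"] <- as.numeric(any(act$drug_class == "insulin"))
  }
  out
}

#' Conditional transformation of HbA1c series
#'
#' Within-subject mean centering of the response and of all time-varying
#' covariates.  This removes the cross-sectional component (baseline level)
#' so that the subsequent mixed-model likelihood depends only on the
#' longitudinal information: adding a constant to one subject's HbA1c
#' leaves the transformed data unchanged.  Subjects with fewer than two
#' visits are excluded (recorded in attribute \code{"excluded"}).
#'
#' @param collection an \code{hba1c_collection} from [generate_hba1c()], or a
#'   list with \code{visits} and \code{medications} data.frames.
#' @return data.frame of class \code{progression_design} with raw and
#'   centered (suffix \code{_c}) columns per visit row.
#' @export
conditional_transform <- function(collection) {
  visits <- collection$visits
  meds <- collection$medications
  need <- c("subject_id", "month", "hba1c")
  if (!all(need %in% names(visits)))
    stopf("visits needs columns: %s", paste(need, collapse = ", "))
  if (is.null(visits$assay_delay)) visits$assay_delay <- 0
  if (is.null(visits$bmi)) visits$bmi <- 0

  cov_rows <- t(vapply(seq_len(nrow(visits)), function(i) {
    sub_meds <- meds[meds$subject_id == visits$subject_id[i], , drop = FALSE]
    dd <- effective_dose(sub_meds, visits$month[i])
    c(dd[["metformin_dose"]], dd[["other_dose"]], dd[["insulin"]])
  }, numeric(3)))
  visits$met_dose <- cov_rows[, 1L]
  visits$met_ind <- as.numeric(visits$met_dose > 0)
  visits$other_dose <- cov_rows[, 2L]
  visits$other_ind <- as.numeric(visits$other_dose > 0)
  visits$insulin_ind <- cov_rows[, 3L]

  counts <- table(visits$subject_id)
  excluded <- names(counts)[counts < 2L]
  if (length(excluded))
    message(sprintf("excluding %d subject(s) with < 2 visits", length(excluded)))
  visits <- visits[!(visits$subject_id %in% excluded), , drop = FALSE]

  center_cols <- c("hba1c", "month", "bmi", "assay_delay", "met_dose",
                   "met_ind", "other_dose", "other_ind", "insulin_ind")
  for (cc in center_cols) {
    mu <- stats::ave(visits[[cc]], visits$subject_id)
    visits[[paste0(cc, "_c")]] <- visits[[cc]] - mu
  }
  attr(visits, "excluded") <- excluded
  class(visits) <- c("progression_design", "data.frame")
  visits
}

# Per-subject contrast representation: multiply each subject's rows by an
# orthonormal basis of the orthogonal complement of the intercept, so the
# singular covariance induced by centering becomes a proper Gaussian.
contrast_blocks <- function(design, fixed_cols) {
  ids <- unique(design$subject_id)
  lapply(ids, function(id) {
    rows <- design[design$subject_id == id, , drop = FALSE]
    ni <- nrow(rows)
    Q <- qr.Q(qr(matrix(1, ni, 1)), complete = TRUE)[, -1L, drop = FALSE]
    list(id = id,
         y = drop(crossprod(Q, rows$hba1c)),
         u = drop(crossprod(Q, rows$month)),
         X = crossprod(Q, as.matrix(rows[fixed_cols])))
  })
}

#' Fit the sign-constrained random-slope progression model
#'
#' Maximum-likelihood estimation of the conditional HbA1c model: per-subject
#' random slope (mmol/mol per month) around a population mean, fixed effects
#' for BMI (constrained \eqn{\ge 0}), metformin (indicator and dose terms,
#' both \eqn{\le 0}), other oral agents (both \eqn{\le 0}), insulin
#' treatment (\eqn{\le 0}) and assay delay (unconstrained), with Gaussian
#' residuals.  Optimization is bound-constrained quasi-Newton (L-BFGS-B)
#' over the fixed effects and log variance components.  Per-subject slopes
#' are returned as empirical-Bayes conditional means; constrained estimates
#' that end on the zero boundary are flagged.
#'
#' @param design a \code{progression_design} from [conditional_transform()].
#' @param constrain apply the sign constraints (default TRUE).
#' @return object of class \code{progression_fit}.
#' @export
fit_progression <- function(design, constrain = TRUE) {
  stopifnot(inherits(design, "progression_design"))
  ids <- unique(design$subject_id)
  if (length(ids) < 10L) stopf("need at least 10 subjects")
  fixed_cols <- c("bmi", "met_ind", "met_dose", "other_ind", "other_dose",
                  "insulin_ind", "assay_delay")
  blocks <- contrast_blocks(design, fixed_cols)
  p <- length(fixed_cols)
  # drop fixed-effect columns with no within-subject variation
  Xall <- do.call(rbind, lapply(blocks, `[[`, "X"))
  keep_fx <- apply(Xall, 2L, function(x) stats::sd(x) > 1e-12)
  fixed_use <- fixed_cols[keep_fx]
  p <- length(fixed_use)
  blocks <- lapply(blocks, function(b) {
    b$X <- b$X[, keep_fx, drop = FALSE]; b
  })

  nll <- function(par) {
    mu <- par[1L]
    beta <- par[seq_len(p) + 1L]
    s2s <- exp(2 * par[p + 2L])
    s2e <- exp(2 * par[p + 3L])
    val <- 0
    for (b in blocks) {
      rr <- b$y - b$u * mu - if (p) drop(b$X %*% beta) else 0
      uu <- sum(b$u^2)
      denom <- s2e + s2s * uu
      quad <- (sum(rr^2) - s2s * sum(b$u * rr)^2 / denom) / s2e
      # b$y is already the (n_i - 1)-dimensional contrast vector
      logdet <- length(b$y) * log(s2e) + log(denom / s2e)
      val <- val + 0.5 * (quad + logdet + length(b$y) * log(2 * pi))
    }
    val
  }

  # starting values from per-subject OLS slopes
  ols <- vapply(blocks, function(b) {
    uu <- sum(b$u^2)
    if (uu < 1e-12) return(c(0, 0))
    s <- sum(b$u * b$y) / uu
    c(s, sum((b$y - b$u * s)^2) / max(length(b$y) - 1, 1))
  }, numeric(2))
  mu0 <- mean(ols[1L, ])
  sig_e0 <- sqrt(max(mean(ols[2L, ]), 1e-4))
  sig_s0 <- sqrt(max(stats::var(ols[1L, ]) - sig_e0^2 / 1000, 1e-6))

  sign_of <- c(bmi = 1, met_ind = -1, met_dose = -1, other_ind = -1,
               other_dose = -1, insulin_ind = -1, assay_delay = 0)[fixed_use]
  lower <- c(-Inf, ifelse(sign_of > 0, 0, -Inf), log(1e-6), log(1e-6))
  upper <- c(Inf, ifelse(sign_of < 0, 0, Inf), log(1e3), log(1e3))
  if (!constrain) {
    lower[seq_len(p) + 1L] <- -Inf
    upper[seq_len(p) + 1L] <- Inf
  }
  start <- c(mu0, ifelse(sign_of > 0, 0.01, ifelse(sign_of < 0, -0.01, 0)),
             log(sig_s0), log(sig_e0))
  start <- pmin(pmax(start, lower + 1e-8), upper - 1e-8)
  fit <- stats::optim(start, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))

  mu <- unname(fit$par[1L])
  beta <- fit$par[seq_len(p) + 1L]
  names(beta) <- fixed_use
  s2s <- unname(exp(2 * fit$par[p + 2L]))
  s2e <- unname(exp(2 * fit$par[p + 3L]))
  slopes <- vapply(blocks, function(b) {
    rr <- b$y - b$u * mu - if (p) drop(b$X %*% beta) else 0
    mu + s2s * sum(b$u * rr) / (s2e + s2s * sum(b$u^2))
  }, 1.0)
  names(slopes) <- vapply(blocks, `[[`, "", "id")

  full_beta <- stats::setNames(rep(NA_real_, length(fixed_cols)), fixed_cols)
  full_beta[fixed_use] <- beta
  boundary <- names(beta)[constrain & sign_of != 0 & abs(beta) < 1e-8]
  structure(list(subject_slopes = slopes, mu_slope = mu,
                 sigma_slope = sqrt(s2s), residual_sd = sqrt(s2e),
                 fixed_effects = full_beta, loglik = -fit$value,
                 converged = fit$convergence == 0, boundary = boundary,
                 constrained = constrain, n_subjects = length(blocks)),
            class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat(sprintf("Constrained random-slope HbA1c progression fit (%d subjects)\n",
              x$n_subjects))
  cat(sprintf("  mean slope %.4f mmol/mol/month (SD %.4f), residual SD %.3f\n",
              x$mu_slope, x$sigma_slope, x$residual_sd))
  fx <- x$fixed_effects[!is.na(x$fixed_effects)]
  cat("  fixed effects:\n")
  for (nm in names(fx)) cat(sprintf("    %-12s %8.4f%s\n", nm, fx[nm],
    if (nm %in% x$boundary) "  [at boundary]" else ""))
  invisible(x)
}

#' Regress adjusted HbA1c slopes on archetype scores
#'
#' One ordinary-least-squares model per archetype score (scores are
#' simplex-collinear, so never fitted jointly), optionally within treatment
#' strata, reporting coefficient, SE, p and 95% CI.
#'
#' @param fit a \code{progression_fit} (or named numeric vector of slopes).
#' @param scores simplex score matrix with subject ids as row names.
#' @param strata optional named factor/character of per-subject strata
#'   (e.g. treated vs untreated); strata with fewer than 10 subjects are
#'   skipped with a warning.
#' @return data.frame: \code{stratum}, \code{archetype}, \code{estimate},
#'   \code{se}, \code{p}, \code{ci_lo}, \code{ci_hi}, \code{n}.
#' @export
slopes_vs_scores <- function(fit, scores, strata = NULL) {
  slopes <- if (inherits(fit, "progression_fit")) fit$subject_slopes else fit
  common <- intersect(names(slopes), rownames(scores))
  if (!length(common)) stopf("no overlapping subjects")
  slopes <- slopes[common]
  scores <- scores[common, , drop = FALSE]
  arch <- colnames(scores) %||% LETTERS[seq_len(ncol(scores))]
  strata_list <- list(all = common)
  if (!is.null(strata)) {
    strata <- strata[common]
    for (lev in unique(strata)) strata_list[[as.character(lev)]] <-
      common[strata == lev]
  }
  rows <- list()
  for (st in names(strata_list)) {
    idx <- strata_list[[st]]
    if (length(idx) < 10L) {
      warning(sprintf("stratum '%s' has < 10 subjects; skipped", st))
      next
    }
    for (a in seq_along(arch)) {
      m <- summary(stats::lm(slopes[idx] ~ scores[idx, a]))
      co <- m$coefficients[2L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, archetype = arch[a], estimate = co[1L], se = co[2L],
        p = co[4L], ci_lo = co[1L] - stats::qt(0.975, m$df[2L]) * co[2L],
        ci_hi = co[1L] + stats::qt(0.975, m$df[2L]) * co[2L],
        n = length(idx), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
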