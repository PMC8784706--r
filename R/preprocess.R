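#' Assemble a phenotype matrix with covariates
#'
#' Light container pairing a complete-case subjects-by-phenotypes numeric
#' matrix with per-subject categorical covariates (sex genotype, recruitment
#' center, ...) and a record of which transformations have been applied.
#'
#' @param values numeric matrix, subjects in rows, phenotypes in columns
#'   (column names required); no missing entries.
#' @param covariates data.frame of per-subject covariates, or NULL.
#' @param transform_state one of \code{"raw"}, \code{"rank_normal"},
#'   \code{"residualized"}.
#' @return object of class \code{phenotype_matrix}.
#' @export
phenotype_matrix <- function(values, covariates = NULL,
                             transform_state = "raw") {
  values <- check_matrix(values, "values")
  if (is.null(colnames(values))) stopf("values must have column names")
  if (ncol(values) == 0L) stopf("values must have at least one column")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      stopf("covariates rows (%d) do not match subjects (%d)",
            nrow(covariates), nrow(values))
  }
  transform_state <- match.arg(transform_state,
                               c("raw", "rank_normal", "residualized"))
  structure(list(values = values, covariates = covariates,
                 transform_state = transform_state),
            class = "phenotype_matrix")
}

#' Rank-based inverse normal transformation of one variable
#'
#' Maps values to standard-normal quantiles of their Blom-offset fractional
#' ranks, \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}.  Ties receive average ranks
#' before the offset.  The map is strictly order-preserving for distinct
#' inputs and symmetric (tie-free input sums to zero).
#'
#' @param column numeric vector, length >= 3, not constant.
#' @param name column name used in error messages.
#' @return transformed numeric vector.
#' @export
rank_inverse_normal <- function(column, name = "column") {
  if (length(column) < 3L) stopf("'%s' has fewer than 3 values", name)
  if (any(!is.finite(column))) stopf("'%s' contains non-finite values", name)
  if (diff(range(column)) == 0)
    stopf("'%s' is constant and cannot be rank-normalized", name)
  r <- rank(column, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(column) + 1 / 4))
}

#' Rank-normalize every column of a phenotype matrix
#'
#' Applies [rank_inverse_normal()] column-wise.  With \code{pool} a list of
#' matrices sharing columns (e.g. several visits), all visits are ranked
#' together in one pooled vector per column and then split back, which keeps
#' follow-up visits on the same scale as baseline.
#'
#' @param x a \code{phenotype_matrix}, or a list of them when \code{pool=TRUE}.
#' @param pool rank all supplied visits jointly before splitting back.
#' @return object(s) with \code{transform_state = "rank_normal"}.
#' @export
rank_normalize <- function(x, pool = FALSE) {
  if (pool) {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "phenotype_matrix")))
    cols <- colnames(x[[1L]]$values)
    for (m in x) if (!identical(colnames(m$values), cols))
      stopf("pooled matrices must share identical columns")
    sizes <- vapply(x, function(m) nrow(m$values), 1L)
    stacked <- do.call(rbind, lapply(x, function(m) m$values))
    for (j in seq_along(cols))
      stacked[, j] <- rank_inverse_normal(stacked[, j], cols[j])
    ends <- cumsum(sizes); starts <- c(1L, utils::head(ends, -1L) + 1L)
    return(lapply(seq_along(x), function(i) {
      out <- x[[i]]
      out$values <- stacked[starts[i]:ends[i], , drop = FALSE]
      out$transform_state <- "rank_normal"
      out
    }))
  }
  stopifnot(inherits(x, "phenotype_matrix"))
  for (j in seq_len(ncol(x$values)))
    x$values[, j] <- rank_inverse_normal(x$values[, j], colnames(x$values)[j])
  x$transform_state <- "rank_normal"
  x
}

#' Residualize phenotypes on covariates by ordinary least squares
#'
#' Replaces each phenotype column by its OLS residual on an intercept plus
#' the named covariates (categorical covariates are one-hot encoded).
#' Residuals are orthogonal to every covariate column; applying the
#' operation twice equals applying it once.
#'
#' @param matrix a \code{phenotype_matrix} carrying the covariates.
#' @param covariate_names character vector of covariate columns to adjust for.
#' @return a \code{phenotype_matrix} with \code{transform_state =
#'   "residualized"}.
#' @export
residualize <- function(matrix, covariate_names) {
  stopifnot(inherits(matrix, "phenotype_matrix"))
  if (is.null(matrix$covariates)) stopf("no covariates attached")
  missing_cov <- setdiff(covariate_names, names(matrix$covariates))
  if (length(missing_cov))
    stopf("covariates not found: %s", paste(missing_cov, collapse = ", "))
  cov <- matrix$covariates[covariate_names]
  if (anyNA(cov)) stopf("covariates contain missing values")
  for (nm in covariate_names)
    if (!is.numeric(cov[[nm]])) cov[[nm]] <- factor(cov[[nm]])
  design <- stats::model.matrix(~ ., data = cov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stopf("covariate design is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  matrix$values <- qr.resid(qrd, matrix$values)
  matrix$transform_state <- "residualized"
  matrix
}

#' Greedy correlation-based pruning of phenotype columns
#'
#' While any pair of columns exceeds \code{cutoff} in absolute Pearson
#' correlation, the pair with the largest |r| is examined and the member
#' with the larger mean absolute correlation to all other remaining columns
#' is dropped (ties drop the later column in input order).  Returns the
#' retained column names in their original order.
#'
#' @param matrix a \code{phenotype_matrix} (or plain numeric matrix).
#' @param cutoff absolute correlation threshold in (0, 1).
#' @return character vector of retained column names.
#' @export
prune_by_correlation <- function(matrix, cutoff) {
  X <- if (inherits(matrix, "phenotype_matrix")) matrix$values else
    check_matrix(matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!(cutoff > 0 && cutoff < 1)) stopf("cutoff must lie in (0, 1)")
  keep <- seq_len(ncol(X))
  R <- abs(stats::cor(X))
  diag(R) <- 0
  while (length(keep) > 1L) {
    Rk <- R[keep, keep, drop = FALSE]
    mx <- max(Rk)
    if (mx <= cutoff) break
    hit <- which(Rk == mx, arr.ind = TRUE)[1L, ]
    i <- keep[hit[1L]]; j <- keep[hit[2L]]
    mean_i <- mean(R[i, setdiff(keep, i)])
    mean_j <- mean(R[j, setdiff(keep, j)])
    drop <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  colnames(X)[keep]
}
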