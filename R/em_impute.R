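#' EM imputation of missing questionnaire items
#'
#' Replaces missing entries of a numeric item-response matrix with their
#' conditional expectations under a multivariate-normal working model,
#' iterating mean/covariance estimation and conditional-mean imputation
#' until successive imputations change by less than `tol`. Observed entries
#' are never touched. Intended for the small amounts of item-level
#' missingness (well under 5%) typical of questionnaire data; higher
#' missingness is an error and listwise deletion is advised instead.
#'
#' @param x Numeric matrix or data frame (rows = respondents, columns =
#'   items) with `NA` for missing entries.
#' @param max_missing Maximum tolerated fraction of missing entries.
#' @param tol Convergence tolerance on the largest absolute change in any
#'   imputed value.
#' @param max_iter Iteration cap.
#' @return A completed numeric matrix.
#' @export
em_impute_items <- function(x, max_missing = 0.05, tol = 1e-6,
                            max_iter = 200L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  miss <- is.na(x)
  if (!any(miss)) return(x)
  frac <- mean(miss)
  if (frac > max_missing) {
    abort(sprintf(paste0("%.1f%% of entries are missing (ceiling %.1f%%); ",
                         "use listwise deletion instead"),
                  100 * frac, 100 * max_missing))
  }
  if (sum(stats::complete.cases(x)) < 10L) {
    abort("EM imputation needs >= 10 complete rows")
  }
  # start from column means
  filled <- x
  for (j in seq_len(ncol(x))) {
    filled[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
  }
  rows <- which(rowSums(miss) > 0L)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(filled)
    sigma <- stats::cov(filled)
    prev <- filled
    for (i in rows) {
      m <- miss[i, ]
      soo <- sigma[!m, !m, drop = FALSE] +
        diag(1e-10, sum(!m))  # guard against singular observed blocks
      smo <- sigma[m, !m, drop = FALSE]
      filled[i, m] <- mu[m] +
        smo %*% solve(soo, filled[i, !m] - mu[!m])
    }
    if (max(abs(filled - prev)) < tol) break
  }
  filled
}
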