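#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-estimator R-hat for one scalar quantity monitored across
#' parallel chains: with `m` chains of length `n`, within-chain variance
#' `W` (mean of chain variances) and between-chain variance `B = n *
#' var(chain means)`, the pooled estimate is `Vhat = (n - 1) / n * W + B / n`
#' and `Rhat = sqrt(Vhat / W)`. Values at or very close to 1.00 indicate
#' the chains are sampling the same distribution.
#'
#' @param chains A numeric matrix (iterations x chains) or list of equal
#'   length numeric vectors, one per chain; at least 2 chains of length
#'   >= 2.
#' @return The R-hat value, or `NA` (with a warning) when the within-chain
#'   variance is zero and the statistic is undefined.
#' @examples
#' set.seed(1)
#' gelman_rubin(matrix(rnorm(4000), ncol = 4))
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1L) abort("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2L || n < 2L) abort("need >= 2 chains of length >= 2")
  w <- mean(apply(chains, 2, var))
  if (w < .Machine$double.eps) {
    warn("within-chain variance is zero; R-hat undefined")
    return(NA_real_)
  }
  b_over_n <- var(colMeans(chains))
  v_hat <- (n - 1) / n * w + b_over_n
  sqrt(v_hat / w)
}

# Spectral density at frequency zero, estimated from an AR fit selected by
# AIC: S(0) = sigma2_innovation / (1 - sum(phi))^2. Returns NA for a
# (near-)constant series.
spectrum0_ar <- function(x) {
  if (var(x) < .Machine$double.eps) return(NA_real_)
  fit <- ar(x, aic = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke stationarity diagnostic
#'
#' Compares the mean of an early window of a chain with the mean of a late
#' window, standardised by spectral-density-at-zero variance estimates:
#' `z = (mean_first - mean_last) / sqrt(S1/n1 + S2/n2)`. Under
#' stationarity `z` is approximately standard normal; |z| > 3 flags a chain
#' still drifting after burn-in.
#'
#' @param chain Numeric vector of post-burn-in draws from a single chain.
#' @param first_fraction,last_fraction Fractions of the chain used for the
#'   early and late windows (defaults 0.1 and 0.5).
#' @return The z-score, or `NA` (with a warning) for a degenerate constant
#'   chain.
#' @export
geweke <- function(chain, first_fraction = 0.1, last_fraction = 0.5) {
  stopifnot(first_fraction > 0, last_fraction > 0,
            first_fraction + last_fraction <= 1)
  n <- length(chain)
  n1 <- floor(first_fraction * n)
  n2 <- floor(last_fraction * n)
  if (n1 < 10L || n2 < 10L) {
    abort("chain too short: both Geweke windows need >= 10 draws")
  }
  x1 <- chain[seq_len(n1)]
  x2 <- chain[seq.int(n - n2 + 1L, n)]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  if (is.na(s1) || is.na(s2)) {
    warn("constant chain segment; Geweke z undefined")
    return(NA_real_)
  }
  (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
}

#' MCMC draw bookkeeping
#'
#' Kept-draw accounting for a multi-chain run: each chain contributes
#' `iterations` post-burn-in draws, so the combined posterior sample holds
#' `chains * iterations` draws.
#'
#' @param chains Number of parallel chains.
#' @param iterations Kept iterations per chain (after burn-in).
#' @param burn_in Discarded iterations per chain.
#' @return A tibble: `chains`, `iterations`, `burn_in`, `total_per_chain`,
#'   `total_kept`.
#' @examples
#' mcmc_plan(chains = 4, iterations = 75000, burn_in = 25000)
#' @export
mcmc_plan <- function(chains, iterations, burn_in) {
  stopifnot(chains >= 1, iterations >= 1, burn_in >= 0)
  tibble(chains = as.integer(chains), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in),
         total_per_chain = as.integer(iterations + burn_in),
         total_kept = as.integer(chains) * as.integer(iterations))
}
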