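#' Central credible interval from posterior draws
#'
#' The empirical `(1 - level)/2` and `1 - (1 - level)/2` quantiles, i.e.
#' the upper and lower limits of the middle `level` of the distribution.
#' Quantiles use linear interpolation between order statistics (R's default
#' type 7 rule), fixed so intervals are reproducible across callers.
#'
#' @param draws Numeric vector of >= 100 finite posterior draws.
#' @param level Credible level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' credible_interval(1:100)  # c(3.475, 97.525)
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100L) abort("need >= 100 draws for a credible interval")
  if (any(!is.finite(draws))) abort("non-finite draws present")
  stopifnot(level > 0, level < 1)
  q <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Screen demographic covariates against an outcome
#'
#' Flags demographics whose correlation with the outcome is suggestive at
#' p < 0.10 (Pearson for continuous measures; for a 0/1 indicator this is
#' the point-biserial correlation, the same computation). Constant columns
#' are excluded with a warning.
#'
#' @param data Tibble holding the outcome and candidate columns.
#' @param outcome Name of the outcome column.
#' @param candidates Names of candidate demographic columns.
#' @param p_threshold Selection gate (default 0.10).
#' @return A tibble: `covariate`, `estimate` (correlation), `p.value`,
#'   `selected`.
#' @export
covariate_screen <- function(data, outcome, candidates = c("age", "gender"),
                             p_threshold = 0.10) {
  if (nrow(data) < 10L) abort("covariate screening needs n >= 10")
  y <- data[[outcome]]
  purrr::map_dfr(candidates, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(paste0("no column named ", v))
    if (var(x, na.rm = TRUE) < .Machine$double.eps) {
      warn(paste0("constant covariate excluded: ", v))
      return(tibble(covariate = v, estimate = NA_real_, p.value = NA_real_,
                    selected = FALSE))
    }
    ct <- cor.test(x, y)
    tibble(covariate = v, estimate = unname(ct$estimate),
           p.value = ct$p.value, selected = ct$p.value < p_threshold)
  })
}

#' Treat fixed parameter values as a degenerate posterior
#'
#' Wraps a per-subject parameter table as a point-mass posterior so the
#' propagation machinery of [propagate_regression()] can run on fixed
#' designs (every iteration sees the same parameter values).
#'
#' @param params Tibble: `subject_id` plus `retention`, `consistency`,
#'   `attn_losses`, `attn_magnitude`.
#' @return A `pvl_point_posterior` object.
#' @export
point_posterior <- function(params) {
  stopifnot(all(c("subject_id", pvl_param_names()) %in% names(params)))
  structure(list(subject_ids = params$subject_id,
                 values = as.matrix(params[, pvl_param_names()])),
            class = "pvl_point_posterior")
}

# number of stored posterior draws and a draw accessor shared by the two
# posterior flavours
posterior_ndraws <- function(fit) {
  if (inherits(fit, "pvl_point_posterior")) 1L
  else fit$iterations * fit$chains
}

# subjects x 4 matrix of PVL parameters at stored draw `idx` (1-based over
# iterations within chains, chain-major), restricted to `sel` subjects
posterior_param_draw <- function(fit, idx, sel) {
  if (inherits(fit, "pvl_point_posterior")) {
    return(fit$values[sel, , drop = FALSE])
  }
  ni <- fit$iterations
  ch <- (idx - 1L) %/% ni + 1L
  it <- (idx - 1L) %% ni + 1L
  m <- matrix(fit$subject[it, ch, , ], ncol = 4L)
  m[sel, , drop = FALSE]
}

#' Bayesian regression on PVL parameters with posterior propagation
#'
#' Regresses a per-subject outcome on the four PVL decision parameters
#' (plus optional demographic covariates) while carrying the full PVL
#' posterior uncertainty through to the regression: each MCMC iteration
#' first takes one stored joint draw of all subjects' PVL parameters
#' (preserving cross-subject posterior correlation), rebuilds the design
#' matrix, and then draws the regression parameters conditional on it.
#' Coefficients get improper uniform priors; the residual variance gets an
#' Inverse-Gamma prior with shape and scale 3 (mean 1.5, variance 2.25).
#'
#' Two conditional-draw backends are available: `"conditional"` draws
#' (sigma2, beta) exactly from their known conditional structure under
#' these priors, and `"mh"` uses random-walk Metropolis-Hastings steps
#' within each iteration; both target the same posterior and agree on
#' posterior means within Monte-Carlo error. The stream of PVL draw indices
#' is generated per chain before any regression randomness, so different
#' regression specifications run under the same seed reuse identical PVL
#' parameter draws.
#'
#' @param pvl_fit A `pvl_hba_fit` or [point_posterior()].
#' @param outcomes Tibble with `subject_id`, the outcome column, and any
#'   covariate columns. Subjects with missing outcomes are dropped with a
#'   message; zero outcome variance is an error, as is n <= predictors + 2.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @param chains,iterations,burn_in MCMC layout (kept iterations per chain).
#' @param seed Integer master seed.
#' @param method `"conditional"` (exact conditional draws) or `"mh"`.
#' @param var_shape,var_scale Inverse-Gamma prior on the residual variance.
#' @param standardize Standardize predictors and outcome before fitting
#'   (default `FALSE`: natural scales).
#' @param mh_steps Inner Metropolis-Hastings updates per iteration when
#'   `method = "mh"`.
#' @return A `pvl_regression` object; see [tidy.pvl_regression()].
#' @export
propagate_regression <- function(pvl_fit, outcomes, outcome = "outcome",
                                 covariates = character(), chains = 4L,
                                 iterations = 2000L, burn_in = 500L, seed,
                                 method = c("conditional", "mh"),
                                 var_shape = 3, var_scale = 3,
                                 standardize = FALSE, mh_steps = 10L) {
  method <- match.arg(method)
  if (missing(seed)) abort("an explicit seed is required")
  stopifnot(chains >= 2L, iterations >= 1L, burn_in >= 0L)
  keep <- !is.na(outcomes[[outcome]])
  if (any(!keep)) {
    inform(paste0("dropping ", sum(!keep), " subject(s) with missing outcome"))
    outcomes <- outcomes[keep, ]
  }
  sel <- match(outcomes$subject_id, pvl_fit$subject_ids)
  if (any(is.na(sel))) {
    inform(paste0("dropping ", sum(is.na(sel)),
                  " subject(s) without PVL posterior draws"))
    outcomes <- outcomes[!is.na(sel), ]
    sel <- sel[!is.na(sel)]
  }
  y <- as.numeric(outcomes[[outcome]])
  n <- length(y)
  if (n < 3L || var(y) < .Machine$double.eps) {
    abort("outcome has (near-)zero variance or too few subjects")
  }
  covm <- NULL
  if (length(covariates) > 0L) {
    covm <- as.matrix(outcomes[, covariates, drop = FALSE])
    storage.mode(covm) <- "double"
  }
  terms <- c("(Intercept)", pvl_param_names(), covariates)
  k <- length(terms)
  if (n <= k + 2L) abort("need n > predictors + 2 for a proper posterior")
  scl <- list(y_mu = 0, y_sd = 1)
  if (standardize) {
    scl <- list(y_mu = mean(y), y_sd = sd(y))
    y <- (y - scl$y_mu) / scl$y_sd
  }
  nd <- posterior_ndraws(pvl_fit)
  total <- iterations + burn_in
  res <- purrr::map(seq_len(chains), function(chn) {
    set.seed(derive_seed(seed, 100L + chn))
    # PVL index stream drawn first: identical across regression specs
    idx_stream <- sample.int(nd, total, replace = TRUE)
    beta_keep <- matrix(NA_real_, iterations, k)
    sig2_keep <- numeric(iterations)
    beta_cur <- NULL
    sig2_cur <- 1
    step_beta <- NULL
    step_ls2 <- 0.3
    acc <- 0
    for (it in seq_len(total)) {
      pm <- posterior_param_draw(pvl_fit, idx_stream[it], sel)
      if (standardize) pm <- scale(pm)
      X <- cbind(1, pm, covm)
      fit0 <- lm.fit(X, y)
      bhat <- fit0$coefficients
      sse <- sum(fit0$residuals^2)
      R <- qr.R(fit0$qr)  # X = QR, X'X = R'R
      if (method == "conditional") {
        sig2_cur <- rinvgamma(1, var_shape + (n - k) / 2,
                              var_scale + sse / 2)
        z <- rnorm(k)
        beta_cur <- bhat + backsolve(R, z) * sqrt(sig2_cur)
      } else {
        if (is.null(beta_cur)) {
          beta_cur <- bhat
          step_beta <- sqrt(diag(chol2inv(R))) * sqrt(sse / (n - k)) * 2.4 /
            sqrt(k)
        }
        lpost <- function(b, s2) {
          -n / 2 * log(s2) - sum((y - X %*% b)^2) / (2 * s2) +
            log_dinvgamma(s2, var_shape, var_scale)
        }
        cur_lp <- lpost(beta_cur, sig2_cur)
        for (s in seq_len(mh_steps)) {
          bp <- beta_cur + step_beta * rnorm(k)
          ls2p <- log(sig2_cur) + step_ls2 * rnorm(1)
          s2p <- exp(ls2p)
          lr <- lpost(bp, s2p) - cur_lp + ls2p - log(sig2_cur)
          if (is.finite(lr) && log(runif(1)) < lr) {
            beta_cur <- bp
            sig2_cur <- s2p
            cur_lp <- lpost(beta_cur, sig2_cur)
            acc <- acc + 1
          }
        }
        if (it <= burn_in && it %% 20L == 0L) {
          rate <- acc / (20 * mh_steps)
          f <- if (rate > 0.3) 1.2 else if (rate < 0.15) 0.8 else 1
          step_beta <- step_beta * f
          step_ls2 <- step_ls2 * f
          acc <- 0
        }
      }
      if (it > burn_in) {
        beta_keep[it - burn_in, ] <- beta_cur
        sig2_keep[it - burn_in] <- sig2_cur
      }
    }
    list(beta = beta_keep, sig2 = sig2_keep)
  })
  beta <- array(NA_real_, c(iterations, chains, k))
  sig2 <- matrix(NA_real_, iterations, chains)
  for (i in seq_len(chains)) {
    beta[, i, ] <- res[[i]]$beta
    sig2[, i] <- res[[i]]$sig2
  }
  structure(list(terms = terms, beta = beta, sigma2 = sig2,
                 outcome = outcome, covariates = covariates,
                 method = method, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), seed = seed, n = n,
                 standardize = standardize, scale = scl,
                 var_shape = var_shape, var_scale = var_scale),
            class = "pvl_regression")
}

#' @export
print.pvl_regression <- function(x, ...) {
  cat("Posterior-propagated Bayesian regression of", x$outcome, "\n")
  cat(sprintf("  n = %d, %d chains x %d kept (%d burn-in), %s draws\n",
              x$n, x$chains, x$iterations, x$burn_in, x$method))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a propagated regression
#'
#' One row per regression term: posterior mean, posterior SD
#' (`std.error`), central credible interval and Gelman-Rubin R-hat across
#' chains.
#'
#' @param x A `pvl_regression`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pvl_regression
#' @export
tidy.pvl_regression <- function(x, level = 0.95, ...) {
  purrr::map_dfr(seq_along(x$terms), function(j) {
    draws <- x$beta[, , j]
    ci <- credible_interval(as.numeric(draws), level)
    tibble(term = x$terms[j], estimate = mean(draws), std.error = sd(draws),
           conf.low = ci[[1]], conf.high = ci[[2]],
           rhat = gelman_rubin(draws))
  })
}

#' @rdname tidy.pvl_regression
#' @method glance pvl_regression
#' @export
glance.pvl_regression <- function(x, ...) {
  td <- tidy(x)
  gw <- regression_geweke(x)
  tibble(nobs = x$n, chains = x$chains,
         draws = x$chains * x$iterations,
         sigma = mean(sqrt(x$sigma2)),
         max_rhat = max(td$rhat, na.rm = TRUE),
         max_abs_geweke = max(abs(gw$z), na.rm = TRUE),
         method = x$method)
}

#' Geweke diagnostics for every coefficient chain
#'
#' @param x A `pvl_regression`.
#' @return A tibble: `term`, `chain`, `z`.
#' @export
regression_geweke <- function(x) {
  purrr::map_dfr(seq_along(x$terms), function(j) {
    purrr::map_dfr(seq_len(x$chains), function(chn) {
      tibble(term = x$terms[j], chain = chn,
             z = geweke(x$beta[, chn, j]))
    })
  })
}

#' Coefficient interval plot for a propagated regression
#'
#' @param object A `pvl_regression`.
#' @param intercept Include the intercept row?
#' @param ... Unused.
#' @return A ggplot object of posterior means with 95% credible intervals.
#' @method autoplot pvl_regression
#' @export
autoplot.pvl_regression <- function(object, intercept = FALSE, ...) {
  td <- tidy(object)
  if (!intercept) td <- filter(td, .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Exploratory correlations with Bonferroni correction
#'
#' Zero-order Pearson correlations of one or more variables with one or
#' more outcomes, with the Bonferroni-adjusted significance gate
#' `alpha / k` over the `k` tests performed.
#'
#' @param data A tibble.
#' @param x_vars,y_vars Column names to correlate (all pairs).
#' @param alpha Familywise error rate before correction.
#' @return A tibble: `x`, `y`, `estimate`, `p.value`, `p_threshold`,
#'   `significant`.
#' @export
exploratory_correlations <- function(data, x_vars, y_vars, alpha = 0.05) {
  k <- length(x_vars) * length(y_vars)
  out <- purrr::map_dfr(x_vars, function(xv) {
    purrr::map_dfr(y_vars, function(yv) {
      ct <- cor.test(data[[xv]], data[[yv]])
      tibble(x = xv, y = yv, estimate = unname(ct$estimate),
             p.value = ct$p.value)
    })
  })
  mutate(out, p_threshold = alpha / k, significant = .data$p.value < alpha / k)
}
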