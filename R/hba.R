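#' Hierarchical prior for PVL parameters
#'
#' Individual parameters are modelled as independent normal distributions
#' truncated to each parameter's range; the group-level means get uniform
#' priors over the same ranges and the group-level variances get
#' Inverse-Gamma priors with shape 5 and scale 1 (prior mean 0.25), which
#' keeps prior variance mass realistic rather than heavy-tailed.
#'
#' @param var_shape,var_scale Inverse-Gamma shape and scale for the group
#'   variances; both must be positive.
#' @return An object of class `hba_prior`.
#' @export
hba_prior <- function(var_shape = 5, var_scale = 1) {
  stopifnot(var_shape > 0, var_scale > 0)
  structure(list(var_shape = var_shape, var_scale = var_scale),
            class = "hba_prior")
}

# log density of x under N(mu, sd^2) truncated to [lo, hi]
log_dtruncnorm <- function(x, mu, sd, lo, hi) {
  z <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  dnorm(x, mu, sd, log = TRUE) - log(z)
}

# log Inverse-Gamma(shape, scale) density up to a constant
log_dinvgamma <- function(x, shape, scale) {
  -(shape + 1) * log(x) - scale / x
}

#' Draw from an inverse-gamma distribution
#' @param n Number of draws.
#' @param shape,scale Inverse-Gamma parameters.
#' @return Positive draws; `1 / rgamma(n, shape, rate = scale)`.
#' @export
rinvgamma <- function(n, shape, scale) 1 / rgamma(n, shape, rate = scale)

# One chain of the adaptive Metropolis-within-Gibbs sampler. Subjects are
# updated one parameter column at a time with a shared proposal scale
# (subjects are conditionally independent, so acceptance is per subject);
# group means and variances get scalar random-walk updates. Proposal scales
# adapt in batches of 50 during burn-in only.
run_hba_chain <- function(dat, model, prior, iterations, burn_in, seed,
                          init_retry = 20L) {
  set.seed(seed)
  rng <- pvl_param_ranges(model)
  lo <- rng$lower
  hi <- rng$upper
  width <- hi - lo
  n <- length(dat$ids)
  decay <- model$learning == "decay"
  ti <- model$choice == "ti"

  loglik <- function(theta) {
    cpp_pvl_loglik(dat$deck, dat$x, dat$start, dat$len, theta, decay, ti)
  }

  # initialization: range midpoints, IG prior mean variance, jittered
  for (try in seq_len(init_retry)) {
    mu <- lo + width / 2 + 0.05 * width * rnorm(4)
    mu <- pmin(pmax(mu, lo + 0.05 * width), hi - 0.05 * width)
    sig2 <- prior$var_scale / (prior$var_shape - 1) * exp(0.2 * rnorm(4))
    theta <- matrix(rep(mu, each = n), n, 4) +
      0.05 * matrix(rnorm(4 * n), n, 4) %*% diag(width)
    theta <- pmin(pmax(theta, matrix(lo + 1e-3 * width, n, 4, byrow = TRUE)),
                  matrix(hi - 1e-3 * width, n, 4, byrow = TRUE))
    ll <- loglik(theta)
    if (all(is.finite(ll))) break
    if (try == init_retry) abort("could not find a finite initial state")
  }

  s_sub <- 0.15 * width
  s_mu <- 0.1 * width
  s_ls2 <- rep(0.4, 4)
  acc_sub <- acc_mu <- acc_ls2 <- numeric(4)
  batch <- 0L

  total <- iterations + burn_in
  keep_mu <- matrix(NA_real_, iterations, 4)
  keep_s2 <- matrix(NA_real_, iterations, 4)
  keep_th <- array(NA_real_, c(iterations, n, 4))

  sdv <- sqrt(sig2)
  for (it in seq_len(total)) {
    # subject-level parameters, one column at a time
    for (p in 1:4) {
      prop <- theta
      prop[, p] <- theta[, p] + s_sub[p] * rnorm(n)
      inb <- prop[, p] >= lo[p] & prop[, p] <= hi[p]
      if (any(inb)) {
        ll_new <- loglik(prop)
        logr <- (ll_new - ll) +
          dnorm(prop[, p], mu[p], sdv[p], log = TRUE) -
          dnorm(theta[, p], mu[p], sdv[p], log = TRUE)
        acc <- inb & is.finite(ll_new) & log(runif(n)) < logr
        theta[acc, p] <- prop[acc, p]
        ll[acc] <- ll_new[acc]
        acc_sub[p] <- acc_sub[p] + mean(acc)
      }
    }
    # group means (uniform prior over the range)
    for (p in 1:4) {
      mp <- mu[p] + s_mu[p] * rnorm(1)
      if (mp >= lo[p] && mp <= hi[p]) {
        logr <- sum(log_dtruncnorm(theta[, p], mp, sdv[p], lo[p], hi[p])) -
          sum(log_dtruncnorm(theta[, p], mu[p], sdv[p], lo[p], hi[p]))
        if (log(runif(1)) < logr) {
          mu[p] <- mp
          acc_mu[p] <- acc_mu[p] + 1
        }
      }
    }
    # group variances (Inverse-Gamma prior), random walk on log sigma^2
    for (p in 1:4) {
      ls2 <- log(sig2[p]) + s_ls2[p] * rnorm(1)
      s2p <- exp(ls2)
      sdp <- sqrt(s2p)
      logr <- sum(log_dtruncnorm(theta[, p], mu[p], sdp, lo[p], hi[p])) -
        sum(log_dtruncnorm(theta[, p], mu[p], sdv[p], lo[p], hi[p])) +
        log_dinvgamma(s2p, prior$var_shape, prior$var_scale) -
        log_dinvgamma(sig2[p], prior$var_shape, prior$var_scale) +
        ls2 - log(sig2[p])  # Jacobian of the log transform
      if (is.finite(logr) && log(runif(1)) < logr) {
        sig2[p] <- s2p
        sdv[p] <- sdp
        acc_ls2[p] <- acc_ls2[p] + 1
      }
    }
    # batch adaptation during burn-in
    if (it <= burn_in && it %% 50L == 0L) {
      batch <- batch + 1L
      tune <- function(s, rate, lo_t = 0.2, hi_t = 0.45) {
        ifelse(rate > hi_t, s * 1.25, ifelse(rate < lo_t, s * 0.8, s))
      }
      s_sub <- tune(s_sub, acc_sub / 50)
      s_mu <- tune(s_mu, acc_mu / 50)
      s_ls2 <- tune(s_ls2, acc_ls2 / 50)
      acc_sub <- acc_mu <- acc_ls2 <- numeric(4)
    }
    if (it > burn_in) {
      k <- it - burn_in
      keep_mu[k, ] <- mu
      keep_s2[k, ] <- sig2
      keep_th[k, , ] <- theta
    }
  }
  list(mu = keep_mu, sig2 = keep_s2, theta = keep_th)
}

data_fingerprint <- function(dat) {
  c(n = length(dat$ids), trials = length(dat$deck),
    deck_sum = sum(dat$deck), net_sum = round(sum(dat$x), 9))
}

#' Fit a PVL model by hierarchical Bayesian MCMC
#'
#' Jointly estimates subject-level PVL parameters and group-level means and
#' variances under the truncated-normal hierarchy of [hba_prior()], using an
#' adaptive Metropolis-within-Gibbs sampler over the compiled likelihood.
#' Chains are initialised at jittered range midpoints (group variances at
#' the Inverse-Gamma prior mean) and are fully reproducible from `seed`.
#' Desk-scale defaults keep 2,000 draws per chain after 1,000 burn-in across
#' 4 chains; study-scale settings (e.g. 4 x 75,000 kept after 25,000
#' burn-in, 300,000 combined draws) are plain argument changes, see
#' [mcmc_plan()].
#'
#' @param trials Trial tibble for >= 2 subjects.
#' @param model A [pvl_model()].
#' @param prior An [hba_prior()].
#' @param chains Number of chains (>= 2).
#' @param iterations Kept iterations per chain.
#' @param burn_in Discarded iterations per chain.
#' @param seed Integer master seed (each chain derives its own stream).
#' @param outcome_scale Points per utility-scale unit.
#' @return A `pvl_hba_fit` object; see [tidy.pvl_hba_fit()],
#'   [subject_estimates()], [pvl_dic()].
#' @export
fit_pvl_hba <- function(trials, model = pvl_model(), prior = hba_prior(),
                        chains = 4L, iterations = 2000L, burn_in = 1000L,
                        seed, outcome_scale = 100) {
  if (missing(seed)) abort("an explicit seed is required")
  stopifnot(chains >= 2L, iterations >= 1L, burn_in >= 0L)
  dat <- prepare_pvl_data(trials, outcome_scale)
  if (length(dat$ids) < 2L) abort("hierarchical fitting needs >= 2 subjects")
  res <- purrr::map(seq_len(chains), function(ch) {
    run_hba_chain(dat, model, prior, iterations, burn_in,
                  seed = derive_seed(seed, ch))
  })
  n <- length(dat$ids)
  fit <- structure(list(
    model = model, prior = prior, subject_ids = dat$ids,
    chains = as.integer(chains), iterations = as.integer(iterations),
    burn_in = as.integer(burn_in), seed = seed,
    outcome_scale = outcome_scale,
    group_mu = abind3(purrr::map(res, "mu")),        # (iter, chain, 4)
    group_var = abind3(purrr::map(res, "sig2")),     # (iter, chain, 4)
    subject = abind4(purrr::map(res, "theta")),      # (iter, chain, n, 4)
    fingerprint = data_fingerprint(dat)
  ), class = "pvl_hba_fit")
  fit
}

# stack chain matrices/arrays along a new chain dimension
abind3 <- function(mats) {
  out <- array(NA_real_, c(nrow(mats[[1]]), length(mats), ncol(mats[[1]])))
  for (i in seq_along(mats)) out[, i, ] <- mats[[i]]
  out
}

abind4 <- function(arrs) {
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(d[1], length(arrs), d[2], d[3]))
  for (i in seq_along(arrs)) out[, i, , ] <- arrs[[i]]
  out
}

#' @export
print.pvl_hba_fit <- function(x, ...) {
  cat("Hierarchical Bayesian PVL fit:", x$model$name, "\n")
  cat(sprintf("  %d subjects, %d chains x %d kept (%d burn-in), %d draws\n",
              length(x$subject_ids), x$chains, x$iterations, x$burn_in,
              x$chains * x$iterations))
  print(tidy(x), n = 8)
  invisible(x)
}

#' Tidy group-level posterior summaries
#'
#' One row per group-level quantity (`mu_*`, `sigma2_*` for each of the four
#' decision parameters): posterior mean, SD, central 95% credible interval
#' and Gelman-Rubin R-hat across chains.
#'
#' @param x A `pvl_hba_fit`.
#' @param level Credible level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pvl_hba_fit
#' @export
tidy.pvl_hba_fit <- function(x, level = 0.95, ...) {
  pn <- pvl_param_names()
  purrr::map_dfr(1:2, function(which) {
    arr <- if (which == 1) x$group_mu else x$group_var
    prefix <- if (which == 1) "mu_" else "sigma2_"
    purrr::map_dfr(1:4, function(p) {
      draws <- arr[, , p, drop = FALSE]
      ci <- credible_interval(as.numeric(draws), level)
      tibble(term = paste0(prefix, pn[p]),
             estimate = mean(draws),
             std.error = sd(draws),
             conf.low = ci[[1]], conf.high = ci[[2]],
             rhat = gelman_rubin(matrix(draws, dim(arr)[1], dim(arr)[2])))
    })
  })
}

#' @rdname tidy.pvl_hba_fit
#' @method glance pvl_hba_fit
#' @export
glance.pvl_hba_fit <- function(x, ...) {
  tibble(model = x$model$name, n_subjects = length(x$subject_ids),
         chains = x$chains, iterations = x$iterations, burn_in = x$burn_in,
         total_kept = x$chains * x$iterations,
         max_rhat = max(tidy(x)$rhat, na.rm = TRUE))
}

#' Convergence gate on a fitted model
#'
#' Checks the Gelman-Rubin statistics of all monitored group-level
#' quantities against two thresholds: values above `warn` trigger a
#' warning, values above `fail` an error. Well-converged runs sit at or
#' very close to 1.00.
#'
#' @param fit A `pvl_hba_fit`.
#' @param warn,fail R-hat thresholds.
#' @return Invisibly, the maximum R-hat.
#' @export
check_convergence <- function(fit, warn = 1.02, fail = 1.1) {
  rh <- tidy(fit)$rhat
  mx <- max(rh, na.rm = TRUE)
  if (mx > fail) {
    abort(sprintf("max R-hat %.3f exceeds failure threshold %.2f", mx, fail))
  }
  if (mx > warn) {
    rlang::warn(sprintf("max R-hat %.3f exceeds %.2f; run longer chains",
                        mx, warn))
  }
  invisible(mx)
}

#' Per-subject posterior parameter estimates
#'
#' @param fit A `pvl_hba_fit`.
#' @param fun Summary applied to each subject x parameter draw vector
#'   (posterior mean by default).
#' @return A tibble: `subject_id` plus the four parameter columns.
#' @export
subject_estimates <- function(fit, fun = mean) {
  est <- apply(fit$subject, c(3, 4), fun)
  colnames(est) <- pvl_param_names()
  dplyr::bind_cols(tibble(subject_id = fit$subject_ids), as_tibble(est))
}

#' Extract posterior draws in long form
#'
#' @param fit A `pvl_hba_fit`.
#' @param pars `"group"` for group-level means/variances or `"subject"` for
#'   subject-level parameters.
#' @return A tibble: `chain`, `iteration`, `parameter` (and `subject_id`
#'   for subject draws), `value`.
#' @export
hba_draws <- function(fit, pars = c("group", "subject")) {
  pars <- match.arg(pars)
  pn <- pvl_param_names()
  ni <- fit$iterations
  nc <- fit$chains
  if (pars == "group") {
    purrr::map_dfr(1:4, function(p) {
      bind_rows(
        tibble(chain = rep(seq_len(nc), each = ni),
               iteration = rep(seq_len(ni), nc),
               parameter = paste0("mu_", pn[p]),
               value = as.numeric(fit$group_mu[, , p])),
        tibble(chain = rep(seq_len(nc), each = ni),
               iteration = rep(seq_len(ni), nc),
               parameter = paste0("sigma2_", pn[p]),
               value = as.numeric(fit$group_var[, , p]))
      )
    })
  } else {
    n <- length(fit$subject_ids)
    purrr::map_dfr(1:4, function(p) {
      tibble(chain = rep(seq_len(nc), each = ni * n) |> as.integer(),
             iteration = rep(rep(seq_len(ni), n), nc),
             subject_id = rep(rep(fit$subject_ids, each = ni), nc),
             parameter = pn[p],
             value = as.numeric(fit$subject[, , , p]))
    })
  }
}

#' Plot group-level posterior densities
#'
#' @param object A `pvl_hba_fit`.
#' @param ... Unused.
#' @return A ggplot object: density of the group-mean draws per parameter,
#'   colour-split by chain.
#' @method autoplot pvl_hba_fit
#' @export
autoplot.pvl_hba_fit <- function(object, ...) {
  draws <- hba_draws(object, "group") %>%
    filter(grepl("^mu_", .data$parameter))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value,
                                      colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "group mean", colour = "chain") +
    ggplot2::theme_minimal()
}
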