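test_that("credible intervals use linear-interpolation quantiles", {
  expect_equal(credible_interval(1:100), c(lower = 3.475, upper = 97.525))
  expect_equal(unname(credible_interval(rep(2.5, 200))), c(2.5, 2.5))
  set.seed(14)
  sym <- rnorm(50000)
  ci <- credible_interval(sym)
  expect_equal(ci[["lower"]], -ci[["upper"]], tolerance = 0.05)
  expect_error(credible_interval(c(1:200, NA)), "non-finite")
  expect_error(credible_interval(1:50), ">= 100")
})

test_that("covariate screening applies the p < 0.10 gate", {
  set.seed(2)
  n <- 500
  dat <- tibble::tibble(outcome = rnorm(n), age = rnorm(n, 40, 10),
                        gender = rbinom(n, 1, 0.3))
  dat$age <- dat$age + 2 * dat$outcome  # strongly associated
  sc <- covariate_screen(dat, "outcome")
  expect_true(sc$selected[sc$covariate == "age"])
  expect_lt(sc$p.value[sc$covariate == "age"], 1e-2)

  dat$flat <- 1
  expect_warning(sc2 <- covariate_screen(dat, "outcome",
                                         c("age", "flat")), "constant")
  expect_false(sc2$selected[sc2$covariate == "flat"])
})

test_that("screening selects an independent demographic at ~ the 10% rate", {
  set.seed(77)
  hits <- purrr::map_lgl(1:400, function(i) {
    y <- rnorm(200)
    x <- rnorm(200)
    cor.test(x, y)$p.value < 0.10
  })
  # package gate must match the same nominal rate
  set.seed(77)
  hits_pkg <- purrr::map_lgl(1:400, function(i) {
    dat <- tibble::tibble(outcome = rnorm(200), age = rnorm(200))
    covariate_screen(dat, "outcome", "age")$selected
  })
  expect_lt(abs(mean(hits_pkg) - 0.10), 0.05)
  expect_equal(mean(hits), mean(hits_pkg), tolerance = 0.06)
})

test_that("point-mass propagation matches the conjugate fixed-design oracle", {
  set.seed(6)
  n <- 200
  cfg <- cohort_config_calibration(n_subjects = n, n_trials = 1,
                                   outcome_coefs = c(intercept = 1,
                                                     attn_losses = -0.5,
                                                     retention = 0.8))
  coh <- generate_cohort(cfg, seed = 61)
  pp <- point_posterior(coh$true_params)
  reg <- propagate_regression(pp, coh$subjects, chains = 4,
                              iterations = 2500, burn_in = 500, seed = 3)
  td <- tidy(reg)
  # under improper uniform beta priors the posterior mean of beta is OLS
  X <- cbind(1, as.matrix(coh$true_params[, -1]))
  bhat <- qr.solve(X, coh$subjects$outcome)
  expect_equal(td$estimate, unname(bhat), tolerance = 0.02)
  # residual-variance posterior matches IG(3 + (n-k)/2, 3 + SSE/2)
  sse <- sum((coh$subjects$outcome - X %*% bhat)^2)
  k <- ncol(X)
  want_mean <- (3 + sse / 2) / (3 + (n - k) / 2 - 1)
  expect_equal(mean(reg$sigma2), want_mean, tolerance = 0.02)
  expect_lt(glance(reg)$max_rhat, 1.02)
})

test_that("exact-conditional and Metropolis-Hastings backends agree", {
  set.seed(9)
  cfg <- cohort_config_calibration(n_subjects = 150, n_trials = 1,
                                   outcome_coefs = c(attn_losses = -0.5))
  coh <- generate_cohort(cfg, seed = 91)
  pp <- point_posterior(coh$true_params)
  a <- propagate_regression(pp, coh$subjects, chains = 4, iterations = 1500,
                            burn_in = 400, seed = 10)
  b <- propagate_regression(pp, coh$subjects, chains = 4, iterations = 1500,
                            burn_in = 400, seed = 10, method = "mh",
                            mh_steps = 20)
  ta <- tidy(a)
  tb <- tidy(b)
  expect_equal(tb$estimate, ta$estimate, tolerance = 0.1)
  expect_true(all(abs(tb$estimate - ta$estimate) < 4 * ta$std.error))
})

test_that("propagating posterior uncertainty never narrows intervals", {
  # one real hierarchical posterior, many outcome replicates: propagated
  # intervals are compared with fixed-design intervals at the per-subject
  # posterior means on the same data
  coh <- generate_cohort(cohort_config_calibration(n_subjects = 16,
                                                   n_trials = 60),
                         seed = 701)
  fit <- fit_pvl_hba(coh$trials, chains = 2, iterations = 250,
                     burn_in = 150, seed = 702)
  # fixed designs are taken at individual posterior draws so their
  # predictor dispersion matches what propagation averages over; by the
  # law of total variance the propagated posterior variance then always
  # dominates the mean conditional variance
  draw_design <- function(i) {
    m <- matrix(fit$subject[50 * i, 1, , ], ncol = 4)
    colnames(m) <- c("retention", "consistency", "attn_losses",
                     "attn_magnitude")
    point_posterior(dplyr::bind_cols(
      tibble::tibble(subject_id = fit$subject_ids), tibble::as_tibble(m)))
  }
  designs <- purrr::map(1:3, draw_design)
  wins <- purrr::map_lgl(1:20, function(rep) {
    set.seed(800 + rep)
    outc <- tibble::tibble(subject_id = coh$true_params$subject_id,
                           outcome = -0.3 * coh$true_params$attn_losses +
                             rnorm(16))
    wf <- mean(purrr::map_dbl(designs, function(pp) {
      fixed <- propagate_regression(pp, outc, chains = 2, iterations = 500,
                                    burn_in = 150, seed = 5)
      sum(with(tidy(fixed), conf.high - conf.low)[2:5])
    }))
    prop <- propagate_regression(fit, outc, chains = 2, iterations = 500,
                                 burn_in = 150, seed = 5)
    wp <- sum(with(tidy(prop), conf.high - conf.low)[2:5])
    wp >= 0.95 * wf
  })
  expect_gte(mean(wins), 0.95)
})

test_that("degenerate regression inputs are refused", {
  cfg <- cohort_config_calibration(n_subjects = 20, n_trials = 1)
  coh <- generate_cohort(cfg, seed = 15)
  pp <- point_posterior(coh$true_params)
  flat <- coh$subjects
  flat$outcome <- 1
  expect_error(propagate_regression(pp, flat, chains = 2, iterations = 200,
                                    burn_in = 50, seed = 1), "variance")
  tiny <- coh$subjects[1:6, ]
  expect_error(propagate_regression(pp, tiny, chains = 2, iterations = 200,
                                    burn_in = 50, seed = 1), "predictors")
  missing <- coh$subjects
  missing$outcome[1:3] <- NA
  expect_message(propagate_regression(pp, missing, chains = 2,
                                      iterations = 200, burn_in = 50,
                                      seed = 1), "dropping 3")
})

test_that("regression runs are reproducible and chains independent", {
  cfg <- cohort_config_calibration(n_subjects = 60, n_trials = 1)
  coh <- generate_cohort(cfg, seed = 33)
  pp <- make_pseudo_posterior(coh$true_params, iterations = 100,
                              chains = 2, seed = 2)
  a <- propagate_regression(pp, coh$subjects, chains = 2, iterations = 300,
                            burn_in = 100, seed = 44)
  b <- propagate_regression(pp, coh$subjects, chains = 2, iterations = 300,
                            burn_in = 100, seed = 44)
  expect_identical(a$beta, b$beta)
  expect_false(identical(a$beta[, 1, ], a$beta[, 2, ]))
  expect_s3_class(autoplot(a), "ggplot")
  gw <- regression_geweke(a)
  expect_equal(nrow(gw), 2L * length(a$terms))
})

test_that("exploratory correlations carry a Bonferroni gate", {
  set.seed(5)
  dat <- tibble::tibble(a = rnorm(300), b = rnorm(300))
  dat$c <- dat$a * 0.9 + rnorm(300, sd = 0.2)
  out <- exploratory_correlations(dat, c("a", "b"), "c")
  expect_equal(out$p_threshold, rep(0.05 / 2, 2))
  expect_true(out$significant[out$x == "a"])
  expect_false(out$significant[out$x == "b"])
})
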