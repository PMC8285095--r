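test_that("utility follows the piecewise prospect-theory form", {
  expect_equal(pvl_utility(0, 0.3, 2), 0)
  expect_equal(pvl_utility(0, 0.9, 0.5), 0)
  expect_equal(pvl_utility(1, 0.5, 2), 1)
  expect_equal(pvl_utility(-1, 0.5, 2), -2)
  expect_equal(pvl_utility(4, 0.5, 1), 2)
  # lambda = 1 gives gain/loss symmetry
  x <- seq(0.1, 10, by = 0.3)
  expect_equal(pvl_utility(-x, 0.7, 1), -pvl_utility(x, 0.7, 1))
  expect_error(pvl_utility(NaN, 0.5, 1), "finite")
})

test_that("utility is monotone in x and weakly decreasing in lambda for losses", {
  x <- seq(-12, 12, by = 0.25)
  for (alpha in c(0.2, 0.6, 1)) {
    u <- pvl_utility(x, alpha, 2.5)
    expect_true(all(diff(u) >= 0))
    u_hi <- pvl_utility(x, alpha, 4)
    expect_true(all(u_hi[x < 0] <= u[x < 0]))
    expect_equal(u_hi[x >= 0], u[x >= 0])
  }
})

test_that("expectancy updating matches both learning rules", {
  E <- c(0.2, -0.1, 0.4, 0)
  expect_equal(pvl_update_expectancies(E, 1, 5, 0, "delta"), E)
  got <- pvl_update_expectancies(E, 2, 5, 1, "delta")
  expect_equal(got[2], 5)
  expect_equal(got[-2], E[-2])
  # hand-iterated delta recursion
  e <- 0
  e <- e + 0.3 * (1 - e)
  expect_equal(e, 0.3)
  e <- e + 0.3 * (1 - e)
  expect_equal(e, 0.51)
  ep <- pvl_update_expectancies(c(0, 0, 0, 0), 3, 1, 0.3, "delta")
  ep <- pvl_update_expectancies(ep, 3, 1, 0.3, "delta")
  expect_equal(ep[3], 0.51)
  # decay: every deck shrinks, chosen gains u
  got <- pvl_update_expectancies(E, 1, 2, 0.25, "decay")
  expect_equal(got, c(0.75 * 0.2 + 2, 0.75 * -0.1, 0.75 * 0.4, 0))
  expect_error(pvl_update_expectancies(E, "E", 1, 0.5, "delta"), "deck")
})

test_that("sensitivity follows the two published transforms", {
  expect_equal(pvl_sensitivity(1:100, 0, "td"), rep(1, 100))
  expect_equal(pvl_sensitivity(10, -3, "td"), 1)
  expect_equal(pvl_sensitivity(10, 4.2, "td"), 1)
  expect_equal(pvl_sensitivity(20, 1, "td"), 2)
  expect_equal(pvl_sensitivity(1:5, 0, "ti"), rep(0, 5))
  expect_equal(pvl_sensitivity(1, 1, "ti"), 2)
  expect_error(pvl_sensitivity(1, 6, "td"), "\\[-5, 5\\]")
  expect_error(pvl_sensitivity(1, -1, "ti"), "\\[0, 5\\]")
})

test_that("choice probabilities are a shift-invariant overflow-safe softmax", {
  expect_equal(pvl_choice_probabilities(c(1, 1, 1, 1), 3), rep(0.25, 4))
  expect_equal(pvl_choice_probabilities(c(9, -4, 0, 2), 0), rep(0.25, 4))
  p <- pvl_choice_probabilities(c(1, 0, 0, 0), 1)
  expect_equal(p[1], exp(1) / (exp(1) + 3), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:25) {
    E <- rnorm(4, sd = 5)
    theta <- runif(1, 0, 10)
    p <- pvl_choice_probabilities(E, theta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(pvl_choice_probabilities(E + 123.4, theta), p,
                 tolerance = 1e-12)
  }
  # extreme theta * E must not overflow
  p <- pvl_choice_probabilities(c(5000, 0, 0, 0), 240)
  expect_equal(p, c(1, 0, 0, 0))
})

test_that("log-likelihood handles the analytic corner cases", {
  params <- tibble::tibble(retention = 0.3, consistency = 0,
                           attn_losses = 1, attn_magnitude = 0.5)
  tr <- trials_from_decks(sample(c("A", "B", "C", "D"), 100, replace = TRUE))
  # trial-independent rule with c = 0: theta = 0, all choices uniform
  ll <- pvl_log_likelihood(params, tr, pvl_model("delta", "ti"))
  expect_equal(ll$loglik, 100 * log(0.25), tolerance = 1e-10)
  # the first trial always contributes log(1/4)
  one <- trials_from_decks("B")
  ll1 <- pvl_log_likelihood(params, one, pvl_model("delta", "td"))
  expect_equal(ll1$loglik, log(0.25), tolerance = 1e-12)
})

test_that("compiled log-likelihood matches the naive per-trial oracle", {
  for (seed in 1:25) {
    case <- random_pvl_case(seed)
    got <- pvl_log_likelihood(case$params, case$trials, case$model)
    tr <- case$trials
    want <- naive_pvl_loglik(match(tr$deck, c("A", "B", "C", "D")),
                             tr$gain - tr$loss,
                             case$params$retention, case$params$consistency,
                             case$params$attn_losses,
                             case$params$attn_magnitude,
                             case$model$learning, case$model$choice)
    expect_equal(got$loglik, want, tolerance = 1e-10)
  }
})

test_that("simulation is seed-reproducible and consistent with its model", {
  params <- tibble::tibble(retention = 0.2, consistency = 0.8,
                           attn_losses = 1.5, attn_magnitude = 0.4)
  a <- simulate_subject(params, pvl_model("delta", "td"), 100, seed = 123)
  b <- simulate_subject(params, pvl_model("delta", "td"), 100, seed = 123)
  expect_identical(a, b)
  ll <- pvl_log_likelihood(params, a, pvl_model("delta", "td"))
  expect_true(is.finite(ll$loglik))

  # trial-independent c = 0: uniform deck frequencies at large n
  unif <- tibble::tibble(retention = 0.2, consistency = 0,
                         attn_losses = 1, attn_magnitude = 0.5)
  tr <- simulate_subject(unif, pvl_model("delta", "ti"), 10000, seed = 5)
  freq <- table(tr$deck) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000) + 0.005))
})

test_that("loss attention drives advantageous choice in simulation", {
  base <- list(retention = 0.2, consistency = 1, attn_magnitude = 0.5)
  prop_adv <- function(lam, seeds) {
    mean(purrr::map_dbl(seeds, function(s) {
      p <- tibble::tibble(retention = base$retention,
                          consistency = base$consistency,
                          attn_losses = lam,
                          attn_magnitude = base$attn_magnitude)
      tr <- simulate_subject(p, pvl_model("delta", "td"), 100, seed = s)
      igt_scores(tr)$prop_advantageous
    }))
  }
  ignore <- prop_adv(0, 1:30)
  averse <- prop_adv(3, 1:30)
  # lambda = 0 produces gain-chasing (preference for the big-gain decks)
  expect_gt(0.5, ignore)
  expect_gt(averse, ignore)
})

test_that("cohort simulation splits streams per subject", {
  params <- tibble::tibble(subject_id = c("a", "b", "c"),
                           retention = c(0.2, 0.3, 0.4),
                           consistency = c(0.5, 0.5, 0.5),
                           attn_losses = c(1, 2, 0.5),
                           attn_magnitude = c(0.5, 0.4, 0.6))
  full <- simulate_cohort(params, n_trials = 30, seed = 77)
  sub <- simulate_cohort(params[1:2, ], n_trials = 30, seed = 77)
  expect_identical(dplyr::filter(full, subject_id %in% c("a", "b")), sub)
})
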