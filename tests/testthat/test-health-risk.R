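test_that("monthly harm scores are harm-weighted day sums", {
  none <- tibble::tibble(subject_id = "s1", month = 1,
                         substance = c("tobacco", "heroin"), days = 0)
  expect_equal(monthly_harm_score(none)$harm_score, 0)

  tob <- tibble::tibble(subject_id = "s1", month = 1,
                        substance = "tobacco", days = 28)
  expect_equal(monthly_harm_score(tob)$harm_score, 37.3 * 28)

  two <- tibble::tibble(subject_id = "s1", month = 1,
                        substance = c("tobacco", "alcohol"),
                        days = c(28, 10))
  expect_equal(monthly_harm_score(two)$harm_score, 37.3 * 28 + 56.1 * 10)

  expect_error(monthly_harm_score(
    tibble::tibble(subject_id = "s1", month = 1, substance = "tea",
                   days = 5)), "tea")
})

test_that("harm scoring is linear over disjoint substance vectors", {
  a <- tibble::tibble(subject_id = "s1", month = 1,
                      substance = c("heroin", "cannabis"), days = c(3, 10))
  b <- tibble::tibble(subject_id = "s1", month = 1,
                      substance = c("alcohol", "ecstasy"), days = c(7, 1))
  expect_equal(monthly_harm_score(dplyr::bind_rows(a, b))$harm_score,
               monthly_harm_score(a)$harm_score +
                 monthly_harm_score(b)$harm_score)
})

test_that("non-28-day months are normalised to a 28-day rate", {
  m <- tibble::tibble(subject_id = "s1", month = 1, substance = "alcohol",
                      days = 15, days_in_month = 30)
  expect_equal(monthly_harm_score(m)$harm_score, 56.1 * 15 * 28 / 30)
})

test_that("the harm composite averages available months", {
  monthly <- tibble::tibble(subject_id = c("a", "a", "b"),
                            month = c(1, 2, 1),
                            harm_score = c(1000, 2000, 500))
  hc <- harm_composite(monthly)
  expect_equal(hc$harm_composite[hc$subject_id == "a"], 1500)
  expect_equal(hc$n_months, c(2L, 1L))
  # a missing month simply drops out of the mean
  with_na <- tibble::tibble(subject_id = "c", month = 1:12,
                            harm_score = c(rep(1200, 11), NA))
  expect_equal(harm_composite(with_na)$harm_composite, 1200)
  expect_equal(harm_composite(with_na)$n_months, 11L)
})

test_that("MAP index dichotomises each behavior over the year", {
  empty <- tibble::tibble(subject_id = "s1", month = 1:12,
                          behavior = "pipe_sharing", occurred = FALSE)
  expect_equal(map_index(empty)$map_index, 0L)

  recurrent <- tibble::tibble(subject_id = "s1", month = 1:7,
                              behavior = "unprotected_sex", occurred = TRUE)
  expect_equal(map_index(recurrent)$map_index, 1L)

  all4 <- tidyr::expand_grid(subject_id = "s1", month = 1:2,
                             behavior = map_behaviors())
  all4$occurred <- TRUE
  expect_equal(map_index(all4)$map_index, 4L)
})

test_that("the Health-risk Index is an exact cohort z-score", {
  comp <- tibble::tibble(subject_id = paste0("s", 1:5),
                         harm_composite = c(100, 900, 2500, 4000, 7000),
                         map_index = c(0, 1, 2, 2, 4))
  out <- health_risk_index(comp)
  expect_lt(abs(mean(out$health_risk_index)), 1e-10)
  expect_lt(abs(sd(out$health_risk_index) - 1), 1e-10)
  # independent spreadsheet-style oracle: z each, average, re-z
  z <- function(x) (x - mean(x)) / sd(x)
  want <- z((z(comp$harm_composite) + z(comp$map_index)) / 2)
  expect_equal(out$health_risk_index, want, tolerance = 1e-12)
  # perfectly correlated components collapse to either z-score
  comp2 <- comp
  comp2$map_index <- comp2$harm_composite / 1000
  out2 <- health_risk_index(comp2)
  expect_equal(out2$health_risk_index, z(comp2$harm_composite),
               tolerance = 1e-12)
  # the alternative combination rule is still a z-score
  alt <- health_risk_index(comp, method = "average_then_z")
  expect_lt(abs(mean(alt$health_risk_index)), 1e-10)
})

test_that("zero-variance index components are named in the error", {
  comp <- tibble::tibble(subject_id = paste0("s", 1:4),
                         harm_composite = c(1, 2, 3, 4), map_index = 2)
  expect_error(health_risk_index(comp), "map_index")
})

test_that("tertile frequency codes respect non-use, balance and ties", {
  expect_equal(frequency_code(rep(0, 6)), rep(0L, 6))
  nine <- frequency_code(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(nine, c(0, 1, 1, 1, 2, 2, 2, 3, 3, 3))
  # tied users straddling a boundary share a code (average-rank rule)
  tied <- frequency_code(c(1, 2, 2, 2, 3, 4, 5))
  expect_equal(tied, c(1, 2, 2, 2, 3, 3, 3))
  # invariance to strictly monotone transforms
  f <- c(0, 0.2, 1.7, 1.7, 2.0, 9.5, 28)
  expect_equal(frequency_code(f), frequency_code(sqrt(f)))
  expect_equal(frequency_code(f), frequency_code(f^3))
})

test_that("per-substance codes work end to end on a fixture cohort", {
  use <- tidyr::expand_grid(subject_id = paste0("s", 1:5), month = 1:2,
                            substance = c("tobacco", "heroin"))
  # row order: month varies before substance within subject
  use$days <- c(28, 0, 28, 0,   # s1: tobacco heavy, no heroin
                20, 2, 22, 2,   # s2
                10, 6, 12, 4,   # s3
                0, 9, 0, 9,     # s4
                5, 0, 3, 0)     # s5
  codes <- substance_frequency_codes(use)
  expect_equal(codes$code_tobacco[codes$subject_id == "s1"], 3L)
  expect_equal(codes$code_tobacco[codes$subject_id == "s4"], 0L)
  expect_equal(codes$code_heroin[codes$subject_id == "s4"], 3L)
  beh <- tidyr::expand_grid(subject_id = paste0("s", 1:5), month = 1:2,
                            behavior = map_behaviors())
  set.seed(1)
  beh$occurred <- runif(nrow(beh)) < 0.3
  out <- health_risk_outcomes(use, beh)
  expect_equal(nrow(out), 5L)
  expect_lt(abs(mean(out$health_risk_index)), 1e-10)
})

test_that("EM imputation reproduces conditional-normal expectations", {
  set.seed(10)
  n <- 60
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  mat <- cbind(x1, x2)
  expect_identical(em_impute_items(mat), mat)

  holed <- mat
  holed[1, 2] <- NA
  out <- em_impute_items(holed)
  expect_equal(out[-1, ], mat[-1, ])
  # independent fixed-point oracle for a single missing entry
  v <- mean(mat[-1, 2])
  for (i in 1:500) {
    filled <- holed
    filled[1, 2] <- v
    mu <- colMeans(filled)
    sg <- stats::cov(filled)
    v_new <- mu[2] + sg[2, 1] / sg[1, 1] * (holed[1, 1] - mu[1])
    if (abs(v_new - v) < 1e-12) break
    v <- v_new
  }
  expect_equal(unname(out[1, 2]), unname(v), tolerance = 1e-5)

  # a column exactly uncorrelated with the rest imputes at its mean
  set.seed(11)
  z <- matrix(rnorm(300), ncol = 3)
  z[, 3] <- stats::residuals(lm(z[, 3] ~ z[, 1] + z[, 2]))
  z2 <- z
  z2[5, 3] <- NA
  got <- em_impute_items(z2)
  # within leave-one-out covariance wobble of the column mean
  expect_lt(abs(got[5, 3] - mean(z[-5, 3])), 0.15)
})

test_that("EM imputation enforces its preconditions", {
  m <- matrix(rnorm(40), ncol = 2)
  m[1:15, 1] <- NA
  expect_error(em_impute_items(m), "listwise")
  small <- matrix(rnorm(10), ncol = 2)
  small[1, 1] <- NA
  expect_error(em_impute_items(small, max_missing = 0.5), "complete rows")
})
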