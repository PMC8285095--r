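#' Configure a synthetic cohort
#'
#' Bundles everything needed to generate a fully synthetic study cohort
#' with known ground truth: group-level PVL parameter moments (subject
#' parameters are drawn from normals truncated to the parameter ranges),
#' demographic distributions, and a linear outcome model whose
#' coefficients on the decision parameters may be zero (emulating null
#' associations) or any chosen effect size.
#'
#' Two presets mirror the qualitative contrast between a substance-using
#' community cohort (low attention to losses, flat learning) and a
#' calibration cohort of healthy volunteers (near-symmetric loss
#' weighting): see [cohort_config_community()] and
#' [cohort_config_calibration()].
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials IGT trials per subject.
#' @param model A [pvl_model()].
#' @param param_means,param_sds Named numeric vectors over `retention`,
#'   `consistency`, `attn_losses`, `attn_magnitude`; means must lie inside
#'   the parameter ranges, SDs must be positive.
#' @param age_mean,age_sd,prop_female Demographic distributions (age in
#'   years; gender coded 1 = female, 0 = male).
#' @param outcome_coefs Named numeric vector of linear-model coefficients:
#'   `intercept`, the four parameter names, `age`, `gender`. Missing names
#'   default to 0.
#' @param residual_sd Outcome noise SD (> 0).
#' @param sss_cor Target correlation between the outcome and a generated
#'   standardized sensation-seeking score.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 100L, n_trials = 100L,
                          model = pvl_model("delta", "td"),
                          param_means = c(retention = 0.21,
                                          consistency = 0.35,
                                          attn_losses = 0.19,
                                          attn_magnitude = 0.56),
                          param_sds = c(retention = 0.21,
                                        consistency = 0.58,
                                        attn_losses = 0.08,
                                        attn_magnitude = 0.27),
                          age_mean = 43, age_sd = 9.5, prop_female = 0.21,
                          outcome_coefs = c(intercept = 0), residual_sd = 1,
                          sss_cor = 0.28) {
  stopifnot(n_subjects >= 2L, n_trials >= 1L, residual_sd > 0,
            all(param_sds > 0), prop_female >= 0, prop_female <= 1,
            abs(sss_cor) < 1)
  pn <- pvl_param_names()
  stopifnot(all(pn %in% names(param_means)), all(pn %in% names(param_sds)))
  rng <- pvl_param_ranges(model)
  inside <- param_means[pn] >= rng$lower & param_means[pn] <= rng$upper
  if (!all(inside)) abort("param_means must lie inside the parameter ranges")
  coefs <- setNames(numeric(7), c("intercept", pn, "age", "gender"))
  coefs[names(outcome_coefs)] <- outcome_coefs
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), model = model,
                 param_means = param_means[pn], param_sds = param_sds[pn],
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female, outcome_coefs = coefs,
                 residual_sd = residual_sd, sss_cor = sss_cor),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @export
cohort_config_community <- function(...) {
  args <- list(...)
  defaults <- list(
    param_means = c(retention = 0.21, consistency = 0.35,
                    attn_losses = 0.19, attn_magnitude = 0.56),
    param_sds = c(retention = 0.21, consistency = 0.58,
                  attn_losses = 0.08, attn_magnitude = 0.27),
    age_mean = 43, age_sd = 9.5, prop_female = 0.21
  )
  do.call(cohort_config, utils::modifyList(defaults, args))
}

#' @rdname cohort_config
#' @export
cohort_config_calibration <- function(...) {
  args <- list(...)
  defaults <- list(
    param_means = c(retention = 0.17, consistency = 0.36,
                    attn_losses = 0.89, attn_magnitude = 0.43),
    param_sds = c(retention = 0.13, consistency = 0.53,
                  attn_losses = 0.62, attn_magnitude = 0.21),
    age_mean = 22, age_sd = 6.5, prop_female = 0.70
  )
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Truncated-normal subject parameters; errors out when the configured
# moments leave less than 1% prior mass inside the range (a pathological
# configuration rather than a sampling problem).
draw_true_params <- function(config, seed) {
  rng <- pvl_param_ranges(config$model)
  mass <- pnorm(rng$upper, config$param_means, config$param_sds) -
    pnorm(rng$lower, config$param_means, config$param_sds)
  if (any(mass < 0.01)) {
    abort("configured group moments put < 1% mass inside a parameter range")
  }
  n <- config$n_subjects
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    out[i, ] <- truncnorm::rtruncnorm(4, a = rng$lower, b = rng$upper,
                                      mean = config$param_means,
                                      sd = config$param_sds)
  }
  colnames(out) <- pvl_param_names()
  dplyr::bind_cols(
    tibble(subject_id = sprintf("s%03d", seq_len(n))),
    as_tibble(out)
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject PVL parameters from truncated normals with the
#' configured group moments, simulates each subject's IGT choice sequence
#' from those parameters under the configured model variant, generates
#' demographics, and builds outcomes from the configured linear model plus
#' normal noise. All randomness derives from the master seed through
#' per-subject, per-domain sub-streams, so regenerating with the same
#' config and seed reproduces the cohort exactly and adding subjects never
#' perturbs existing ones.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @param schedule Payoff schedule.
#' @return A `synthetic_cohort` list: `true_params`, `trials`, `subjects`
#'   (demographics + `outcome` + `sensation_seeking`), `config`, `seed`.
#' @export
generate_cohort <- function(config, seed, schedule = igt_payoff_schedule()) {
  if (missing(seed)) abort("an explicit seed is required")
  true_params <- draw_true_params(config, derive_seed(seed, 10001L))
  trials <- simulate_cohort(true_params, config$model, config$n_trials,
                            seed = derive_seed(seed, 10002L),
                            schedule = schedule)
  n <- config$n_subjects
  set.seed(derive_seed(seed, 10003L))
  age <- rnorm(n, config$age_mean, config$age_sd)
  gender <- rbinom(n, 1L, config$prop_female)
  b <- config$outcome_coefs
  mu <- b["intercept"] +
    as.matrix(true_params[, pvl_param_names()]) %*% b[pvl_param_names()] +
    b["age"] * age + b["gender"] * gender
  set.seed(derive_seed(seed, 10004L))
  outcome <- as.numeric(mu) + rnorm(n, 0, config$residual_sd)
  set.seed(derive_seed(seed, 10005L))
  r <- config$sss_cor
  zo <- as.numeric(scale(outcome))
  sss <- r * zo + sqrt(1 - r^2) * rnorm(n)
  subjects <- tibble(subject_id = true_params$subject_id, age = age,
                     gender = gender, outcome = outcome,
                     sensation_seeking = sss)
  structure(list(true_params = true_params, trials = trials,
                 subjects = subjects, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic IGT cohort:", x$config$n_subjects, "subjects x",
      x$config$n_trials, "trials,", x$config$model$name,
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Default synthetic substance-use configuration
#'
#' Per-substance prevalence of any use during the observation year and the
#' typical days-per-month rate among users, alongside the harm indices.
#' Prevalences follow the reported rates in a precariously housed
#' community cohort (tobacco and alcohol near-universal, hallucinogens
#' rare); days rates are round per-month values consistent with the
#' reported medians and IQRs.
#'
#' @return A tibble: `substance`, `prevalence`, `mean_days`.
#' @export
default_substances <- function() {
  tibble(
    substance = c("tobacco", "alcohol", "crack_cocaine", "cannabis",
                  "heroin", "powder_cocaine", "methadone_prescribed",
                  "methamphetamine", "amphetamine",
                  "methadone_nonprescribed", "ecstasy", "lsd", "ghb",
                  "ketamine"),
    prevalence = c(0.923, 0.792, 0.768, 0.730, 0.495, 0.440, 0.431, 0.430,
                   0.089, 0.055, 0.051, 0.014, 0.014, 0.010),
    mean_days = c(26, 6, 9, 9, 7, 3, 24, 4, 2, 3, 1, 1, 1, 1)
  )
}

#' Default risk-behavior prevalences
#'
#' Probability that a subject reports each behavior at least once during
#' the year (pipe-sharing and injection common, needle-sharing rare).
#'
#' @return A tibble: `behavior`, `prevalence`.
#' @export
default_behaviors <- function() {
  tibble(behavior = map_behaviors(),
         prevalence = c(0.054, 0.354, 0.616, 0.622))
}

#' Generate synthetic substance-use and risk-behavior tables
#'
#' Monthly days of use are zero-inflated: each subject is a user of a
#' substance with the configured prevalence; users' monthly days are
#' binomial out of 28 around a personal rate (so counts live in [0, 28] by
#' construction and a mean of 28 sits exactly at the ceiling), and users
#' are guaranteed at least one use-day in the year. Behaviors are drawn
#' analogously: an engaging subject (configured prevalence) reports the
#' behavior in at least one month. Each subject has an independent RNG
#' stream.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param seed Master integer seed.
#' @param substances Tibble like [default_substances()].
#' @param behaviors Tibble like [default_behaviors()].
#' @param n_months Months of follow-up (default 12).
#' @param monthly_rate Probability an engaging subject reports a behavior
#'   in any given month.
#' @return A list with long tibbles `use` (`subject_id`, `month`,
#'   `substance`, `days`) and `behaviors` (`subject_id`, `month`,
#'   `behavior`, `occurred`).
#' @export
generate_substance_tables <- function(subject_ids, seed,
                                      substances = default_substances(),
                                      behaviors = default_behaviors(),
                                      n_months = 12L, monthly_rate = 0.4) {
  if (missing(seed)) abort("an explicit seed is required")
  if (any(substances$prevalence < 0 | substances$prevalence > 1) ||
      any(behaviors$prevalence < 0 | behaviors$prevalence > 1)) {
    abort("prevalence values must lie in [0, 1]")
  }
  ns <- nrow(substances)
  nb <- nrow(behaviors)
  use_list <- beh_list <- vector("list", length(subject_ids))
  for (i in seq_along(subject_ids)) {
    set.seed(derive_seed(seed, 20000L + i))
    user <- runif(ns) < substances$prevalence
    p0 <- pmin(pmax(substances$mean_days / 28, 0), 1)
    # subject-level heterogeneity on the logit scale; p0 of 0 or 1 is exact
    pz <- ifelse(p0 <= 0 | p0 >= 1, p0,
                 stats::plogis(stats::qlogis(p0) + 0.5 * rnorm(ns)))
    days <- matrix(0, n_months, ns)
    for (s in which(user)) {
      d <- rbinom(n_months, 28L, pz[s])
      if (sum(d) == 0) d[sample.int(n_months, 1L)] <- 1
      days[, s] <- d
    }
    use_list[[i]] <- tibble(
      subject_id = subject_ids[i],
      month = rep(seq_len(n_months), ns),
      substance = rep(substances$substance, each = n_months),
      days = as.vector(days)
    )
    engages <- runif(nb) < behaviors$prevalence
    occ <- matrix(FALSE, n_months, nb)
    for (b in which(engages)) {
      o <- runif(n_months) < monthly_rate
      if (!any(o)) o[sample.int(n_months, 1L)] <- TRUE
      occ[, b] <- o
    }
    beh_list[[i]] <- tibble(
      subject_id = subject_ids[i],
      month = rep(seq_len(n_months), nb),
      behavior = rep(behaviors$behavior, each = n_months),
      occurred = as.vector(occ)
    )
  }
  list(use = bind_rows(use_list), behaviors = bind_rows(beh_list))
}
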