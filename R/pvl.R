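#' Specify a PVL model variant
#'
#' The Prospect Valence Learning family crosses two expectancy-updating
#' rules with two softmax choice rules, giving four variants:
#' PVL-Delta-TD, PVL-Delta-TI, PVL-Decay-TD, PVL-Decay-TI.
#'
#' * **delta** updating moves only the chosen deck's expectancy toward the
#'   latest utility by the retention parameter `A` (the learning rate);
#'   **decay** updating shrinks every deck's expectancy by `(1 - A)` and adds
#'   the latest utility to the chosen deck. In both rules larger `A` means
#'   faster updating / shorter retention of past outcomes.
#' * **trial-dependent (td)** sensitivity grows (or shrinks) with trial,
#'   `theta(t) = (t / 10) ^ c` with consistency `c` in `[-5, 5]`;
#'   **trial-independent (ti)** sensitivity is constant,
#'   `theta = 3 ^ c - 1` with `c` in `[0, 5]`.
#'
#' @param learning `"delta"` or `"decay"`.
#' @param choice `"td"` (trial-dependent) or `"ti"` (trial-independent).
#' @return An object of class `pvl_model`.
#' @examples
#' pvl_model("delta", "td")
#' @export
pvl_model <- function(learning = c("delta", "decay"),
                      choice = c("td", "ti")) {
  learning <- match.arg(learning)
  choice <- match.arg(choice)
  structure(
    list(learning = learning, choice = choice,
         name = paste0("PVL-", if (learning == "delta") "Delta" else "Decay",
                       "-", toupper(choice))),
    class = "pvl_model"
  )
}

#' @export
print.pvl_model <- function(x, ...) {
  cat(x$name, "\n", sep = "")
  invisible(x)
}

#' All four PVL model variants
#' @return A named list of [pvl_model()] objects.
#' @export
pvl_model_variants <- function() {
  out <- list(pvl_model("delta", "td"), pvl_model("delta", "ti"),
              pvl_model("decay", "td"), pvl_model("decay", "ti"))
  setNames(out, purrr::map_chr(out, "name"))
}

pvl_param_names <- function() {
  c("retention", "consistency", "attn_losses", "attn_magnitude")
}

#' Parameter ranges for a PVL model variant
#'
#' Closed ranges of the four decision parameters: retention `A` in `[0, 1]`,
#' consistency `c` in `[-5, 5]` (trial-dependent) or `[0, 5]`
#' (trial-independent), attention to losses `lambda` in `[0, 5]`, attention
#' to magnitude `alpha` in `[0, 1]`.
#'
#' @param model A [pvl_model()].
#' @return A tibble: `parameter`, `lower`, `upper`.
#' @export
pvl_param_ranges <- function(model) {
  tibble(
    parameter = pvl_param_names(),
    lower = c(0, if (model$choice == "td") -5 else 0, 0, 0),
    upper = c(1, 5, 5, 1)
  )
}

validate_pvl_params <- function(params, model) {
  rng <- pvl_param_ranges(model)
  for (k in seq_len(nrow(rng))) {
    v <- params[[rng$parameter[k]]]
    if (is.null(v) || any(!is.finite(v))) {
      abort(paste0("missing or non-finite parameter: ", rng$parameter[k]))
    }
    if (any(v < rng$lower[k]) || any(v > rng$upper[k])) {
      abort(paste0(rng$parameter[k], " outside [", rng$lower[k], ", ",
                   rng$upper[k], "] for ", model$name))
    }
  }
  invisible(params)
}

#' Prospect-theory utility of a net outcome
#'
#' `u(x) = x^alpha` for gains and `-lambda * |x|^alpha` for losses, with
#' `u(0) = 0`. `alpha` (attention to magnitude, `[0, 1]`) controls how
#' strongly utility scales with outcome magnitude; `lambda` (attention to
#' losses, `[0, 5]`) weights losses relative to gains, `lambda = 1` giving
#' gain/loss symmetry. `x` is the net outcome on the model's working scale
#' (points divided by `outcome_scale`, see [pvl_log_likelihood()]).
#'
#' @param x Net outcome(s), scaled; must be finite.
#' @param alpha Attention to magnitude, in `[0, 1]`.
#' @param lambda Attention to losses, in `[0, 5]`.
#' @return Utilities, same length as `x`.
#' @examples
#' pvl_utility(c(-1, 0, 1), alpha = 0.5, lambda = 2)
#' @export
pvl_utility <- function(x, alpha, lambda) {
  if (any(!is.finite(x))) abort("x must be finite")
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, lambda <= 5)
  ifelse(x >= 0, x^alpha, -lambda * abs(x)^alpha)
}

#' Update deck expectancies after an outcome
#'
#' @param E Numeric vector of 4 deck expectancies.
#' @param chosen Index (1--4) or label (`"A"`--`"D"`) of the chosen deck.
#' @param u Utility of the obtained outcome.
#' @param A Retention parameter in `[0, 1]`; larger = faster updating.
#' @param learning `"delta"` or `"decay"`.
#' @return The updated expectancy vector.
#' @export
pvl_update_expectancies <- function(E, chosen, u, A,
                                    learning = c("delta", "decay")) {
  learning <- match.arg(learning)
  stopifnot(length(E) == 4L, A >= 0, A <= 1)
  if (is.character(chosen)) chosen <- match(chosen, c("A", "B", "C", "D"))
  if (is.na(chosen) || chosen < 1L || chosen > 4L) {
    abort("chosen deck must be one of A-D")
  }
  if (learning == "delta") {
    E[chosen] <- E[chosen] + A * (u - E[chosen])
  } else {
    E <- (1 - A) * E
    E[chosen] <- E[chosen] + u
  }
  E
}

#' Softmax sensitivity at a trial
#'
#' Trial-dependent: `theta(t) = (t / 10) ^ c`; trial-independent:
#' `theta = 3 ^ c - 1`, constant over trials.
#'
#' @param t Trial index (1-based).
#' @param consistency Consistency parameter `c`.
#' @param choice `"td"` or `"ti"`.
#' @return Non-negative sensitivity value(s).
#' @export
pvl_sensitivity <- function(t, consistency, choice = c("td", "ti")) {
  choice <- match.arg(choice)
  stopifnot(all(t >= 1))
  if (choice == "td") {
    if (consistency < -5 || consistency > 5) {
      abort("consistency must lie in [-5, 5] for the trial-dependent rule")
    }
    (t / 10)^consistency
  } else {
    if (consistency < 0 || consistency > 5) {
      abort("consistency must lie in [0, 5] for the trial-independent rule")
    }
    rep(3^consistency - 1, length(t))
  }
}

#' Softmax choice probabilities over the four decks
#'
#' `P_j = exp(theta E_j) / sum_k exp(theta E_k)`, computed with
#' max-subtraction so extreme `theta * E` cannot overflow.
#'
#' @param E Numeric vector of 4 deck expectancies (finite).
#' @param theta Non-negative sensitivity.
#' @return A probability vector of length 4 summing to 1.
#' @export
pvl_choice_probabilities <- function(E, theta) {
  stopifnot(length(E) == 4L, all(is.finite(E)), theta >= 0)
  z <- theta * E
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

prepare_pvl_data <- function(trials, outcome_scale) {
  trials <- validate_trials(trials)
  trials <- arrange(trials, .data$subject_id, .data$trial)
  deck_idx <- match(trials$deck, c("A", "B", "C", "D"))
  if (any(is.na(deck_idx))) abort("deck labels must be A, B, C or D")
  ids <- unique(trials$subject_id)
  len <- as.integer(table(factor(trials$subject_id, levels = ids)))
  list(
    ids = ids,
    deck = deck_idx - 1L,
    x = trials$net / outcome_scale,
    start = c(0L, cumsum(len)[-length(len)]),
    len = len
  )
}

params_matrix <- function(params, ids, model) {
  validate_pvl_params(params, model)
  if (!"subject_id" %in% names(params)) {
    if (nrow(params) != 1L) abort("params without subject_id must be one row")
    params <- params[rep(1L, length(ids)), ]
    params$subject_id <- ids
  }
  idx <- match(ids, params$subject_id)
  if (any(is.na(idx))) abort("params missing for some subjects in trials")
  as.matrix(params[idx, pvl_param_names()])
}

#' PVL log-likelihood of observed choice sequences
#'
#' Sum over trials of the log softmax probability of each observed choice,
#' with expectancies initialised at zero and updated through the previous
#' trial. Net outcomes are divided by `outcome_scale` (default 100, i.e.
#' hundreds of points) before entering the utility function, which keeps
#' `x^alpha` numerically tame; the constant is recorded in the result.
#'
#' @param params Tibble of decision parameters with columns `retention`,
#'   `consistency`, `attn_losses`, `attn_magnitude` and either a
#'   `subject_id` column matching `trials` or a single row applied to every
#'   subject.
#' @param trials Trial tibble (see [read_igt_trials()]).
#' @param model A [pvl_model()].
#' @param outcome_scale Points per utility-scale unit.
#' @return A tibble: `subject_id`, `loglik`. A choice assigned probability
#'   zero yields `-Inf` for that subject.
#' @export
pvl_log_likelihood <- function(params, trials, model = pvl_model(),
                               outcome_scale = 100) {
  dat <- prepare_pvl_data(trials, outcome_scale)
  pm <- params_matrix(params, dat$ids, model)
  ll <- cpp_pvl_loglik(dat$deck, dat$x, dat$start, dat$len, pm,
                       model$learning == "decay", model$choice == "ti")
  out <- tibble(subject_id = dat$ids, loglik = as.numeric(ll))
  attr(out, "outcome_scale") <- outcome_scale
  out
}

#' Simulate IGT choice sequences from a PVL model
#'
#' Generative counterpart of [pvl_log_likelihood()]: on each trial a deck is
#' sampled from the model's softmax probabilities, the outcome is dealt from
#' the payoff schedule (cycling deterministically within each deck), and
#' expectancies are updated. Identical seeds give identical sequences.
#'
#' @param params One-row tibble (or named list) of decision parameters.
#' @param model A [pvl_model()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; required for reproducibility.
#' @param schedule Payoff schedule tibble.
#' @param subject_id Identifier stamped on the output.
#' @param outcome_scale Points per utility-scale unit.
#' @return A trial tibble: `subject_id`, `trial`, `deck`, `gain`, `loss`,
#'   `net`.
#' @export
simulate_subject <- function(params, model = pvl_model(), n_trials = 100L,
                             seed, schedule = igt_payoff_schedule(),
                             subject_id = "s1", outcome_scale = 100) {
  stopifnot(n_trials >= 1L)
  if (missing(seed)) abort("an explicit seed is required")
  params <- as_tibble(as.list(unlist(params[pvl_param_names()])))
  validate_pvl_params(params, model)
  validate_schedule(schedule)
  A <- params$retention
  cc <- params$consistency
  lam <- params$attn_losses
  alpha <- params$attn_magnitude
  labels <- c("A", "B", "C", "D")
  sched <- purrr::map(labels, function(lab) {
    rows <- schedule[schedule$deck == lab, , drop = FALSE]
    rows[order(rows$position), c("gain", "loss"), drop = FALSE]
  })
  set.seed(seed)
  E <- numeric(4L)
  counts <- integer(4L)
  deck <- integer(n_trials)
  gain <- loss <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    theta <- pvl_sensitivity(t, cc, model$choice)
    p <- pvl_choice_probabilities(E, theta)
    d <- sample.int(4L, 1L, prob = p)
    counts[d] <- counts[d] + 1L
    pos <- ((counts[d] - 1L) %% nrow(sched[[d]])) + 1L
    deck[t] <- d
    gain[t] <- sched[[d]]$gain[pos]
    loss[t] <- sched[[d]]$loss[pos]
    u <- pvl_utility((gain[t] - loss[t]) / outcome_scale, alpha, lam)
    E <- pvl_update_expectancies(E, d, u, A, model$learning)
  }
  tibble(subject_id = subject_id, trial = seq_len(n_trials),
         deck = labels[deck], gain = gain, loss = loss, net = gain - loss)
}

#' Simulate a cohort of subjects
#'
#' Each row of `params` (one subject) gets an independent RNG stream derived
#' from the master seed, so adding subjects never perturbs existing ones.
#'
#' @param params Tibble with `subject_id` plus the four parameter columns.
#' @param seed Master integer seed.
#' @inheritParams simulate_subject
#' @return A trial tibble for all subjects.
#' @export
simulate_cohort <- function(params, model = pvl_model(), n_trials = 100L,
                            seed, schedule = igt_payoff_schedule(),
                            outcome_scale = 100) {
  if (missing(seed)) abort("an explicit seed is required")
  stopifnot("subject_id" %in% names(params))
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    simulate_subject(params[i, ], model, n_trials,
                     seed = derive_seed(seed, i),
                     schedule = schedule,
                     subject_id = params$subject_id[i],
                     outcome_scale = outcome_scale)
  })
}
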