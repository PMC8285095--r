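# Independent oracles and fixture builders shared across the suite.
# The oracle implementations deliberately avoid the package's internals:
# they spell out each recursion step in plain R so the vectorised /
# compiled paths are checked against a second, naive derivation.

# Naive per-trial PVL log-likelihood for one subject.
naive_pvl_loglik <- function(deck, net, A, cc, lam, alpha,
                             learning, choice, outcome_scale = 100) {
  E <- c(0, 0, 0, 0)
  ll <- 0
  for (t in seq_along(deck)) {
    theta <- if (choice == "td") (t / 10)^cc else 3^cc - 1
    z <- theta * E
    d <- deck[t]
    ll <- ll + (z[d] - max(z)) - log(sum(exp(z - max(z))))
    x <- net[t] / outcome_scale
    u <- if (x >= 0) x^alpha else -lam * (-x)^alpha
    if (learning == "delta") {
      E[d] <- E[d] + A * (u - E[d])
    } else {
      E <- (1 - A) * E
      E[d] <- E[d] + u
    }
  }
  ll
}

# A deterministic trial tibble from an explicit deck-label sequence,
# outcomes dealt from the canonical schedule.
trials_from_decks <- function(decks, subject_id = "s1",
                              schedule = igt_payoff_schedule()) {
  counts <- integer(4)
  labels <- c("A", "B", "C", "D")
  gain <- loss <- numeric(length(decks))
  for (t in seq_along(decks)) {
    d <- match(decks[t], labels)
    counts[d] <- counts[d] + 1L
    card <- draw_card(schedule, decks[t], counts[d])
    gain[t] <- card$gain
    loss[t] <- card$loss
  }
  tibble::tibble(subject_id = subject_id, trial = seq_along(decks),
                 deck = decks, gain = gain, loss = loss)
}

random_pvl_case <- function(seed) {
  set.seed(seed)
  model <- pvl_model(sample(c("delta", "decay"), 1),
                     sample(c("td", "ti"), 1))
  rng <- pvl_param_ranges(model)
  vals <- runif(4, rng$lower, rng$upper)
  params <- tibble::tibble(retention = vals[1], consistency = vals[2],
                           attn_losses = vals[3], attn_magnitude = vals[4])
  decks <- sample(c("A", "B", "C", "D"), 100, replace = TRUE)
  list(model = model, params = params,
       trials = trials_from_decks(decks))
}

# A pseudo posterior: truncated-normal jitter around true per-subject
# parameters, shaped like the draw store of a hierarchical fit. Used to
# exercise posterior propagation without paying for an MCMC run.
make_pseudo_posterior <- function(true_params, sd_frac = 0.05,
                                  iterations = 200L, chains = 2L, seed = 1L,
                                  model = pvl_model("delta", "td")) {
  rng <- pvl_param_ranges(model)
  n <- nrow(true_params)
  arr <- array(NA_real_, c(iterations, chains, n, 4))
  set.seed(seed)
  for (p in 1:4) {
    width <- rng$upper[p] - rng$lower[p]
    truth <- true_params[[c("retention", "consistency", "attn_losses",
                            "attn_magnitude")[p]]]
    for (i in seq_len(n)) {
      arr[, , i, p] <- truncnorm::rtruncnorm(iterations * chains,
                                             a = rng$lower[p],
                                             b = rng$upper[p],
                                             mean = truth[i],
                                             sd = sd_frac * width)
    }
  }
  structure(list(subject_ids = true_params$subject_id, subject = arr,
                 iterations = iterations, chains = chains),
            class = "pvl_hba_fit")
}
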