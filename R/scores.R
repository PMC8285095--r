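#' Read and write trial-level IGT data
#'
#' Trial tables are plain CSV with a header and columns `subject_id`,
#' `trial`, `deck`, `gain`, `loss`; `loss` is stored as a non-negative
#' magnitude and the net outcome is always `gain - loss`.
#'
#' @param path File path.
#' @return A tibble of trials with an added `net` column.
#' @export
read_igt_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(subject_id = "c", deck = "c"))
  validate_trials(out)
}

#' @rdname read_igt_trials
#' @param trials A trial tibble.
#' @export
write_igt_trials <- function(trials, path) {
  readr::write_csv(select(trials, "subject_id", "trial", "deck", "gain", "loss"),
                   path)
  invisible(path)
}

validate_trials <- function(trials) {
  need <- c("subject_id", "trial", "deck", "gain", "loss")
  if (!all(need %in% names(trials))) {
    abort(paste0("trial data needs columns ", paste(need, collapse = ", ")))
  }
  if (any(trials$loss < 0)) abort("loss must be a non-negative magnitude")
  ok <- trials %>%
    group_by(.data$subject_id) %>%
    summarise(ok = all(.data$trial == seq_len(n())), .groups = "drop")
  if (!all(ok$ok)) {
    abort("each subject's trials must be numbered 1, 2, ... with no gaps")
  }
  trials <- as_tibble(trials)
  trials$net <- trials$gain - trials$loss
  trials
}

window_prop <- function(deck, trial, from, to, adv) {
  if (max(trial) < to) return(NA_real_)
  sel <- trial >= from & trial <= to
  mean(deck[sel] %in% adv)
}

#' Traditional IGT performance scores
#'
#' Computes, per subject, the proportion of advantageous selections over all
#' trials and in two late windows (trials 41--100, the "last 60", and trials
#' 21--100, after the initial exploratory phase), the total net score
#' (advantageous minus disadvantageous selections), and per-deck selection
#' proportions. Windows that extend beyond a subject's sequence are reported
#' as `NA` rather than extrapolated.
#'
#' @param trials A trial tibble (see [read_igt_trials()]).
#' @param advantageous Deck labels counted as advantageous.
#' @return A tibble with one row per subject: `n_trials`, `prop_advantageous`,
#'   `prop_advantageous_last60`, `prop_advantageous_21_100`, `net_score`,
#'   and `prop_A` ... `prop_D`.
#' @export
igt_scores <- function(trials, advantageous = advantageous_decks()) {
  trials <- validate_trials(trials)
  per_deck <- trials %>%
    count(.data$subject_id, .data$deck) %>%
    group_by(.data$subject_id) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(names_from = "deck", values_from = "prop",
                       names_prefix = "prop_", values_fill = 0)
  for (d in c("A", "B", "C", "D")) {
    col <- paste0("prop_", d)
    if (!col %in% names(per_deck)) per_deck[[col]] <- 0
  }
  base <- trials %>%
    group_by(.data$subject_id) %>%
    summarise(
      n_trials = n(),
      prop_advantageous = mean(.data$deck %in% advantageous),
      prop_advantageous_last60 =
        window_prop(.data$deck, .data$trial, 41L, 100L, advantageous),
      prop_advantageous_21_100 =
        window_prop(.data$deck, .data$trial, 21L, 100L, advantageous),
      net_score = sum(.data$deck %in% advantageous) -
        sum(!.data$deck %in% advantageous),
      .groups = "drop"
    )
  left_join(base, per_deck, by = "subject_id")
}

#' Convert between proportion advantageous and net score
#'
#' The two traditional IGT summaries are linearly equivalent: over `n_trials`
#' trials a proportion `p` of advantageous selections corresponds to a net
#' score of `n_trials * (2 p - 1)`, so percent-advantageous values of 30, 40,
#' 50, 60, 70 and 80 over 100 trials map to net scores of -40, -20, 0, 20,
#' 40 and 60.
#'
#' @param p Proportion of advantageous selections, in `[0, 1]`.
#' @param net Net score (advantageous minus disadvantageous selections).
#' @param n_trials Number of trials.
#' @return A numeric vector.
#' @examples
#' proportion_to_net(0.8, 100)  # 60
#' net_to_proportion(-40, 100)  # 0.3
#' @export
proportion_to_net <- function(p, n_trials) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p must be a proportion in [0, 1]")
  }
  n_trials * (2 * p - 1)
}

#' @rdname proportion_to_net
#' @export
net_to_proportion <- function(net, n_trials) {
  if (any(abs(net) > n_trials)) abort("|net| cannot exceed n_trials")
  (net / n_trials + 1) / 2
}

#' Block learning curves
#'
#' Proportion of advantageous selections in consecutive blocks of
#' `block_size` trials (five blocks of 20 for the standard 100-trial task).
#' A final partial block is dropped with a message.
#'
#' @inheritParams igt_scores
#' @param block_size Trials per block.
#' @return A long tibble: `subject_id`, `block`, `prop_advantageous`.
#' @export
igt_block_curve <- function(trials, block_size = 20L,
                            advantageous = advantageous_decks()) {
  trials <- validate_trials(trials)
  trials <- mutate(trials, block = (.data$trial - 1L) %/% block_size + 1L)
  full <- trials %>%
    count(.data$subject_id, .data$block) %>%
    filter(.data$n == block_size)
  dropped <- anti_join_n(trials, full)
  if (dropped > 0L) {
    inform(paste0("dropping ", dropped, " trial(s) in partial final blocks"))
  }
  trials %>%
    inner_join_blocks(full) %>%
    group_by(.data$subject_id, .data$block) %>%
    summarise(prop_advantageous = mean(.data$deck %in% advantageous),
              .groups = "drop")
}

anti_join_n <- function(trials, full) {
  nrow(dplyr::anti_join(trials, full, by = c("subject_id", "block")))
}

inner_join_blocks <- function(trials, full) {
  dplyr::inner_join(trials, select(full, -"n"), by = c("subject_id", "block"))
}

#' Polynomial trend contrasts over blocks
#'
#' Repeated-measures polynomial trend tests on block learning curves:
#' orthogonal polynomial contrasts are scored per subject and each contrast
#' is tested against its within-subject error (a one-sample F with
#' df = (1, n - 1)), the standard way linear/quadratic/cubic learning trends
#' are assessed across five blocks of 20 trials.
#'
#' @param block_curve Long tibble from [igt_block_curve()], or a numeric
#'   matrix of subjects x blocks.
#' @return A tibble: `trend`, `estimate` (mean contrast score), `statistic`
#'   (F), `df1`, `df2`, `p.value`. Subjects missing any block are excluded
#'   with a message.
#' @export
block_trend_contrasts <- function(block_curve) {
  if (is.matrix(block_curve)) {
    m <- block_curve
  } else {
    wide <- tidyr::pivot_wider(block_curve, names_from = "block",
                               values_from = "prop_advantageous")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide$subject_id)
  }
  keep <- stats::complete.cases(m)
  if (any(!keep)) {
    inform(paste0("excluding ", sum(!keep),
                  " subject(s) with missing blocks from trend contrasts"))
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  b <- ncol(m)
  if (n < 2L) abort("trend contrasts need at least 2 complete subjects")
  if (b < 2L) abort("trend contrasts need at least 2 blocks")
  contr <- stats::contr.poly(b)
  labels <- c("linear", "quadratic", "cubic", "quartic", "quintic")
  purrr::map_dfr(seq_len(b - 1L), function(k) {
    s <- as.numeric(m %*% contr[, k])
    v <- var(s)
    f <- if (v < 1e-24) {
      if (abs(mean(s)) < 1e-12) 0 else Inf
    } else {
      n * mean(s)^2 / v
    }
    tibble(
      trend = if (k <= length(labels)) labels[k] else paste0("degree_", k),
      estimate = mean(s), statistic = f, df1 = 1L, df2 = n - 1L,
      p.value = stats::pf(f, 1, n - 1, lower.tail = FALSE)
    )
  })
}

#' Plot block learning curves
#'
#' Mean proportion of advantageous selections per block with 95% normal
#' confidence intervals across subjects, optionally split by a grouping
#' column carried in `block_curve`.
#'
#' @param block_curve Long tibble from [igt_block_curve()]; may carry an
#'   extra grouping column named by `group`.
#' @param group Optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_block_curves <- function(block_curve, group = NULL) {
  grp <- if (!is.null(group)) block_curve[[group]] else "all"
  dat <- block_curve %>%
    mutate(.group = grp) %>%
    group_by(.data$.group, .data$block) %>%
    summarise(mean = mean(.data$prop_advantageous),
              se = sd(.data$prop_advantageous) / sqrt(n()),
              .groups = "drop")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$block, y = .data$mean,
                                         colour = .data$.group,
                                         group = .data$.group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                          ymax = .data$mean + 1.96 * .data$se)) +
    ggplot2::labs(x = "Block of 20 trials", y = "Proportion advantageous",
                  colour = group %||% NULL) +
    ggplot2::theme_minimal()
  if (is.null(group)) p <- p + ggplot2::guides(colour = "none")
  p
}
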