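#' The canonical IGT payoff schedule
#'
#' Returns the classic four-deck Iowa Gambling Task payoff structure as a
#' tibble with one row per (deck, position) in the deck's repeating 10-card
#' cycle. Decks A and B pay a constant 100 points per card but lose 1250
#' points per 10 cards (net -250); decks C and D pay 50 points per card and
#' lose only 250 per 10 cards (net +250). Deck losses differ in frequency:
#' A and C lose on five cards per cycle, B and D on a single card.
#'
#' Any alternative schedule with the same columns (`deck`, `position`,
#' `gain`, `loss`) can be used wherever a schedule is accepted; see
#' [read_payoff_schedule()].
#'
#' @return A tibble with columns `deck` (`"A"`--`"D"`), `position` (1-based
#'   position in the cycle), `gain` and `loss` (points; `loss` is a
#'   non-negative magnitude).
#' @examples
#' sched <- igt_payoff_schedule()
#' # defining advantage structure: net per 10 draws
#' dplyr::count(sched, deck, wt = gain - loss)
#' @export
igt_payoff_schedule <- function() {
  a_loss <- c(0, 0, 150, 0, 300, 0, 200, 0, 250, 350)
  b_loss <- c(0, 0, 0, 0, 0, 0, 0, 0, 1250, 0)
  c_loss <- c(0, 0, 50, 0, 50, 0, 50, 0, 50, 50)
  d_loss <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 250)
  tibble(
    deck = rep(c("A", "B", "C", "D"), each = 10L),
    position = rep(1:10, 4L),
    gain = rep(c(100, 100, 50, 50), each = 10L),
    loss = c(a_loss, b_loss, c_loss, d_loss)
  )
}

#' Deck labels considered advantageous
#'
#' Decks C and D: small constant gains, small long-run losses, positive
#' expected net outcome over a full cycle.
#'
#' @return Character vector `c("C", "D")`.
#' @export
advantageous_decks <- function() c("C", "D")

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  need <- c("deck", "position", "gain", "loss")
  if (!all(need %in% names(schedule))) {
    abort(paste0("schedule must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(schedule$gain <= 0)) abort("every schedule position must have gain > 0")
  if (any(schedule$loss < 0)) abort("schedule losses are non-negative magnitudes")
  invisible(schedule)
}

#' Draw one card from a deck
#'
#' Deterministically returns the outcome of the `draw_count`-th draw from a
#' deck: the deck's cycle is dealt in order and repeats, so draw
#' `cycle_length + 1` returns the same card as draw 1.
#'
#' @param schedule A payoff schedule tibble, e.g. [igt_payoff_schedule()].
#' @param deck Deck label, one of `"A"`--`"D"` (or the labels present in
#'   `schedule`).
#' @param draw_count How many times this deck has been chosen so far,
#'   including the current draw; integer >= 1.
#' @return A tibble with one row and columns `gain`, `loss`, `net`.
#' @examples
#' draw_card(igt_payoff_schedule(), "B", 9)   # the big deck-B loss
#' @export
draw_card <- function(schedule, deck, draw_count) {
  validate_schedule(schedule)
  stopifnot(length(deck) == 1L, length(draw_count) == 1L, draw_count >= 1)
  rows <- schedule[schedule$deck == deck, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(paste0("unknown deck label: ", deck))
  }
  rows <- rows[order(rows$position), , drop = FALSE]
  pos <- ((as.integer(draw_count) - 1L) %% nrow(rows)) + 1L
  tibble(gain = rows$gain[pos], loss = rows$loss[pos],
         net = rows$gain[pos] - rows$loss[pos])
}

# Vectorised dealing: outcomes for an ordered sequence of deck choices,
# tracking per-deck draw counts. Returns a tibble aligned with `decks`.
deal_decks <- function(schedule, decks) {
  validate_schedule(schedule)
  labels <- unique(schedule$deck)
  bad <- setdiff(unique(decks), labels)
  if (length(bad) > 0L) abort(paste0("unknown deck label: ", bad[1L]))
  gain <- loss <- numeric(length(decks))
  for (lab in labels) {
    idx <- which(decks == lab)
    if (length(idx) == 0L) next
    rows <- schedule[schedule$deck == lab, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    pos <- ((seq_along(idx) - 1L) %% nrow(rows)) + 1L
    gain[idx] <- rows$gain[pos]
    loss[idx] <- rows$loss[pos]
  }
  tibble(trial = seq_along(decks), deck = decks, gain = gain, loss = loss,
         net = gain - loss)
}

#' Read or write a payoff schedule as CSV
#'
#' Schedules are stored as plain CSV with columns `deck`, `position`,
#' `gain`, `loss` (loss as a non-negative magnitude).
#'
#' @param path File path.
#' @return `read_payoff_schedule()` returns the schedule tibble.
#' @export
read_payoff_schedule <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(deck = "c"))
  validate_schedule(out)
  as_tibble(out)
}

#' @rdname read_payoff_schedule
#' @param schedule A schedule tibble.
#' @export
write_payoff_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  readr::write_csv(schedule, path)
  invisible(path)
}
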