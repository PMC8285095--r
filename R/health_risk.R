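#' Published harm-to-self weights per substance
#'
#' Unitless harm indices used to weight days of use into a monthly harm
#' score. Shipped as plain CSV in `inst/extdata/harm_indices.csv`; both
#' prescribed and non-prescribed methadone carry the same weight, and
#' tobacco is included like any other substance (a configurable exclusion
#' list is available in [monthly_harm_score()]).
#'
#' @return A tibble: `substance`, `harm_index`.
#' @export
harm_indices <- function() {
  path <- system.file("extdata", "harm_indices.csv", package = "pvlbayes")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(substance = "c",
                                          harm_index = "d"))
}

#' Monthly substance-related harm scores
#'
#' For each subject-month, multiplies the harm index of each substance by
#' the days of use of that substance in that (28-day) month and sums across
#' substances. Months reported on a different length (an optional
#' `days_in_month` column) are normalised to a 28-day rate first.
#'
#' @param use Long tibble: `subject_id`, `month`, `substance`, `days`
#'   (0--28), optionally `days_in_month`.
#' @param harm Harm-index tibble (see [harm_indices()]).
#' @param exclude Substances to drop before scoring (default none).
#' @return A tibble: `subject_id`, `month`, `harm_score` (>= 0).
#' @examples
#' use <- tibble::tibble(subject_id = "s1", month = 1,
#'                       substance = "tobacco", days = 28)
#' monthly_harm_score(use)  # 37.3 * 28 = 1044.4
#' @export
monthly_harm_score <- function(use, harm = harm_indices(),
                               exclude = character()) {
  use <- filter(use, !.data$substance %in% exclude)
  if (any(use$days < 0 | use$days > 28)) {
    abort("days of use must lie in [0, 28] per 28-day month")
  }
  missing <- setdiff(unique(use$substance), harm$substance)
  if (length(missing) > 0L) {
    abort(paste0("no harm index for substance(s): ",
                 paste(missing, collapse = ", ")))
  }
  if ("days_in_month" %in% names(use)) {
    use <- mutate(use, days = .data$days * 28 / .data$days_in_month)
  }
  use %>%
    left_join(harm, by = "substance") %>%
    group_by(.data$subject_id, .data$month) %>%
    summarise(harm_score = sum(.data$harm_index * .data$days),
              .groups = "drop")
}

#' Harm composite: mean monthly harm score per subject
#'
#' Averages each subject's monthly harm scores over the months of data
#' available, which stabilises month-to-month variation irrelevant to risk
#' taking.
#'
#' @param monthly Tibble from [monthly_harm_score()].
#' @return A tibble: `subject_id`, `harm_composite`, `n_months`.
#' @export
harm_composite <- function(monthly) {
  monthly %>%
    filter(!is.na(.data$harm_score)) %>%
    group_by(.data$subject_id) %>%
    summarise(harm_composite = mean(.data$harm_score), n_months = n(),
              .groups = "drop")
}

#' The four risk-behavior types of the MAP index
#' @return Character vector of canonical behavior labels.
#' @export
map_behaviors <- function() {
  c("needle_sharing", "unprotected_sex", "pipe_sharing", "injection_drug_use")
}

#' MAP risk-behavior index (0--4)
#'
#' Each of four behavior types (needle-sharing, unprotected sex,
#' pipe-sharing, injection drug use) is dichotomised over the observation
#' year -- zero instances versus at least one, however often it recurred --
#' and the four indicators are summed.
#'
#' @param behaviors Long tibble: `subject_id`, `month`, `behavior`,
#'   `occurred` (logical or 0/1).
#' @param types Behavior labels counted (default [map_behaviors()]).
#' @return A tibble: `subject_id`, `map_index` in 0--4.
#' @export
map_index <- function(behaviors, types = map_behaviors()) {
  if (nrow(behaviors) == 0L) abort("behavior reports must cover >= 1 month")
  behaviors %>%
    filter(.data$behavior %in% types) %>%
    group_by(.data$subject_id, .data$behavior) %>%
    summarise(any = any(as.logical(.data$occurred)), .groups = "drop") %>%
    group_by(.data$subject_id) %>%
    summarise(map_index = as.integer(sum(.data$any)), .groups = "drop")
}

zscore <- function(x, label) {
  s <- sd(x)
  if (s < .Machine$double.eps) {
    abort(paste0("zero variance in component: ", label))
  }
  (x - mean(x)) / s
}

#' Health-risk Index: standardized composite of harm and MAP scores
#'
#' Combines the substance-related harm composite and the MAP behavior
#' count into a single standardized index. The default (`"z_then_average"`)
#' z-scores each component within the cohort, averages the two z-scores per
#' subject, and re-standardises the average so the output is an exact
#' cohort z-score (mean 0, SD 1). The alternative (`"average_then_z"`)
#' averages the raw components first.
#'
#' @param components Tibble with `subject_id`, `harm_composite`,
#'   `map_index` for a cohort of n >= 3.
#' @param method Combination rule, see above.
#' @return The input with an added `health_risk_index` column.
#' @export
health_risk_index <- function(components,
                              method = c("z_then_average",
                                         "average_then_z")) {
  method <- match.arg(method)
  if (nrow(components) < 3L) abort("cohort must have n >= 3")
  h <- components$harm_composite
  m <- components$map_index
  raw <- if (method == "z_then_average") {
    (zscore(h, "harm_composite") + zscore(m, "map_index")) / 2
  } else {
    (h + m) / 2
  }
  mutate(components, health_risk_index = zscore(raw, "combined index"))
}

#' Tertile frequency-of-use codes (0--3)
#'
#' Non-users (frequency zero) are coded 0. Users are rank-ordered by
#' frequency and split into thirds: bottom third 1, middle third 2, top
#' third 3. Ties share an average rank, so equal frequencies always receive
#' the same code (tie integrity takes precedence over exactly balanced
#' group sizes). The coding depends only on ranks, so any strictly
#' monotone transform of the frequencies yields identical codes.
#'
#' @param frequency Numeric vector of non-negative use frequencies (e.g.
#'   mean days of use per month) across a cohort.
#' @return Integer codes 0--3, same length as `frequency`.
#' @export
frequency_code <- function(frequency) {
  stopifnot(all(frequency >= 0))
  code <- integer(length(frequency))
  users <- which(frequency > 0)
  nu <- length(users)
  if (nu == 0L) return(code)
  r <- rank(frequency[users], ties.method = "average")
  code[users] <- 1L + (r > nu / 3) + (r > 2 * nu / 3)
  code
}

#' Per-substance frequency codes for a cohort
#'
#' Computes each subject's mean days of use per month for every substance
#' and applies [frequency_code()] within substance.
#'
#' @param use Long tibble: `subject_id`, `month`, `substance`, `days`.
#' @return A wide tibble: `subject_id` plus one `code_<substance>` column
#'   per substance.
#' @export
substance_frequency_codes <- function(use) {
  use %>%
    group_by(.data$subject_id, .data$substance) %>%
    summarise(freq = mean(.data$days), .groups = "drop") %>%
    group_by(.data$substance) %>%
    mutate(code = frequency_code(.data$freq)) %>%
    ungroup() %>%
    select(-"freq") %>%
    tidyr::pivot_wider(names_from = "substance", values_from = "code",
                       names_prefix = "code_", values_fill = 0L)
}

#' Build the full health-risk outcome table for a cohort
#'
#' Convenience wrapper running the whole construction: monthly harm scores
#' -> harm composite, MAP index, Health-risk Index, and per-substance
#' frequency codes.
#'
#' @param use Long use tibble (`subject_id`, `month`, `substance`, `days`).
#' @param behaviors Long behavior tibble (`subject_id`, `month`,
#'   `behavior`, `occurred`).
#' @inheritParams monthly_harm_score
#' @inheritParams health_risk_index
#' @return A per-subject tibble with `harm_composite`, `n_months`,
#'   `map_index`, `health_risk_index` and the frequency-code columns.
#' @export
health_risk_outcomes <- function(use, behaviors, harm = harm_indices(),
                                 exclude = character(),
                                 method = "z_then_average") {
  comp <- harm_composite(monthly_harm_score(use, harm, exclude))
  mi <- map_index(behaviors)
  out <- left_join(comp, mi, by = "subject_id") %>%
    mutate(map_index = ifelse(is.na(.data$map_index), 0L, .data$map_index))
  out <- health_risk_index(out, method)
  left_join(out, substance_frequency_codes(use), by = "subject_id")
}
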