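#' Deviance information criterion for a fitted PVL model
#'
#' DIC balances fit against complexity: with mean posterior deviance
#' `Dbar` (deviance = -2 x summed log-likelihood over subjects, averaged
#' over posterior draws of the subject-level parameters) and the deviance
#' `Dhat` at the per-subject posterior-mean parameters, the effective
#' number of parameters is `pD = Dbar - Dhat` and `DIC = Dbar + pD =
#' 2 * Dbar - Dhat`. Smaller is better, comparable only across models
#' fitted to the same data.
#'
#' @param fit A `pvl_hba_fit`.
#' @param trials The trial tibble the model was fitted to.
#' @param thin Keep every `thin`-th draw when averaging the deviance.
#' @return A one-row tibble of class `pvl_dic`: `model`, `mean_deviance`,
#'   `deviance_at_mean`, `p_d`, `dic`, `n_draws`, `n_excluded`. Draws with
#'   non-finite deviance are excluded and counted; more than 1% exclusions
#'   is an error.
#' @export
pvl_dic <- function(fit, trials, thin = 1L) {
  dat <- prepare_pvl_data(trials, fit$outcome_scale)
  if (!identical(data_fingerprint(dat), fit$fingerprint)) {
    abort("trials do not match the data this model was fitted to")
  }
  n <- length(dat$ids)
  keep <- seq(1L, fit$iterations, by = thin)
  arr <- fit$subject[keep, , , , drop = FALSE]
  arr <- aperm(arr, c(3, 1, 2, 4))  # subject fastest, then iter, chain
  draws <- matrix(as.vector(arr), ncol = 4L)
  decay <- fit$model$learning == "decay"
  ti <- fit$model$choice == "ti"
  dev <- cpp_pvl_deviance(dat$deck, dat$x, dat$start, dat$len, draws, n,
                          decay, ti)
  bad <- !is.finite(dev)
  if (mean(bad) > 0.01) {
    abort(sprintf("%.1f%% of draws have non-finite deviance", 100 * mean(bad)))
  }
  d_bar <- mean(dev[!bad])
  theta_bar <- apply(fit$subject, c(3, 4), mean)
  d_hat <- as.numeric(cpp_pvl_deviance(dat$deck, dat$x, dat$start, dat$len,
                                       theta_bar, n, decay, ti))
  out <- tibble(model = fit$model$name, mean_deviance = d_bar,
                deviance_at_mean = d_hat, p_d = d_bar - d_hat,
                dic = d_bar + (d_bar - d_hat),
                n_draws = sum(!bad), n_excluded = sum(bad))
  attr(out, "fingerprint") <- fit$fingerprint
  class(out) <- c("pvl_dic", class(out))
  out
}

#' Rank PVL model variants by DIC
#'
#' @param ... `pvl_dic` results (or one list of them), all computed on the
#'   same cohort; mixing cohorts is an error.
#' @return A tibble sorted by ascending DIC with `delta_dic` relative to
#'   the best model.
#' @export
compare_models <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "pvl_dic")) {
    results <- results[[1]]
  }
  fps <- purrr::map(results, attr, "fingerprint")
  if (length(unique(purrr::map_chr(fps, paste, collapse = "|"))) != 1L) {
    abort("DIC results come from different cohorts; comparison is invalid")
  }
  out <- bind_rows(purrr::map(results, as_tibble)) %>%
    arrange(.data$dic) %>%
    mutate(delta_dic = .data$dic - .data$dic[1])
  out
}
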