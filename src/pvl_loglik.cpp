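#include <Rcpp.h>
using namespace Rcpp;

// Sequential PVL log-likelihood for one subject.
// deck: 0-based deck indices in choice order; x: net outcomes already on the
// utility scale (points / outcome_scale). Expectancies start at zero; the
// probability of the choice at trial t uses expectancies updated through t-1
// and the sensitivity theta(t) of the chosen rule.
static double subject_loglik(const int* deck, const double* x, const int T,
                             const double A, const double c, const double lam,
                             const double alpha, const bool decay,
                             const bool trial_independent) {
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  const double theta_ti = trial_independent ? (std::pow(3.0, c) - 1.0) : 0.0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const double theta =
        trial_independent ? theta_ti : std::pow((t + 1) / 10.0, c);
    double z[4], m = -INFINITY;
    for (int j = 0; j < 4; ++j) {
      z[j] = theta * E[j];
      if (z[j] > m) m = z[j];
    }
    double s = 0.0;
    for (int j = 0; j < 4; ++j) s += std::exp(z[j] - m);
    const int d = deck[t];
    ll += z[d] - m - std::log(s);
    const double xt = x[t];
    const double u = (xt >= 0.0) ? std::pow(xt, alpha)
                                 : -lam * std::pow(-xt, alpha);
    if (decay) {
      for (int j = 0; j < 4; ++j) E[j] *= (1.0 - A);
      E[d] += u;
    } else {
      E[d] += A * (u - E[d]);
    }
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_pvl_loglik(IntegerVector deck, NumericVector x,
                             IntegerVector subj_start, IntegerVector subj_len,
                             NumericMatrix params, bool decay,
                             bool trial_independent) {
  const int n = subj_start.size();
  if (params.nrow() != n)
    stop("params must have one row per subject");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = subject_loglik(&deck[subj_start[i]], &x[subj_start[i]],
                            subj_len[i], params(i, 0), params(i, 1),
                            params(i, 2), params(i, 3), decay,
                            trial_independent);
  }
  return out;
}

// Total deviance (-2 * summed log-likelihood) for each of a stack of
// parameter draws; draws is (n_draws*n) x 4 with subject index varying
// fastest. Used for DIC's mean deviance without an R-level loop.
// [[Rcpp::export]]
NumericVector cpp_pvl_deviance(IntegerVector deck, NumericVector x,
                               IntegerVector subj_start, IntegerVector subj_len,
                               NumericMatrix draws, int n_subjects, bool decay,
                               bool trial_independent) {
  const int n_draws = draws.nrow() / n_subjects;
  if (n_draws * n_subjects != draws.nrow())
    stop("draws rows must be a multiple of n_subjects");
  NumericVector out(n_draws);
  for (int k = 0; k < n_draws; ++k) {
    double tot = 0.0;
    for (int i = 0; i < n_subjects; ++i) {
      const int r = k * n_subjects + i;
      tot += subject_loglik(&deck[subj_start[i]], &x[subj_start[i]],
                            subj_len[i], draws(r, 0), draws(r, 1), draws(r, 2),
                            draws(r, 3), decay, trial_independent);
    }
    out[k] = -2.0 * tot;
  }
  return out;
}
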