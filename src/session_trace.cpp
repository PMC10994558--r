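#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential belief-trace / log-likelihood kernel for one session.
//
// choice: 1-based chosen bandit, NA on missed trials
// outcome: observed payout, NA on missed trials
// missed: per-trial missed flag
// learning: 0 = delta rule, 1 = Bayesian (Kalman) learner
// bonus_type: 0 = posterior SD, 1 = posterior variance (Bayesian only;
//   delta variants use the recency count as the uncertainty term)
//
// Per trial: softmax probabilities from the pre-trial beliefs; on valid
// trials the choice log-probability accumulates and the observation
// update runs; recency counters advance on every trial; the Bayesian
// diffusion (prediction) step runs after every trial.
// [[Rcpp::export]]
List session_trace_cpp(IntegerVector choice, NumericVector outcome,
                       IntegerVector missed, int n_bandits,
                       int learning, bool use_explore, bool use_persev,
                       int bonus_type,
                       double alpha, double beta, double phi, double rho,
                       double decay, double center,
                       double diffusion_sd, double observation_sd,
                       double prior_mean, double prior_var,
                       bool trace) {
  const int nt = choice.size();
  std::vector<double> Q(n_bandits, prior_mean);
  std::vector<double> V(n_bandits, prior_var);
  std::vector<double> tsc(n_bandits, 0.0);
  int last = -1;
  double ll = 0.0;
  const double obs_var = observation_sd * observation_sd;
  const double diff_var = diffusion_sd * diffusion_sd;

  NumericMatrix Qm, Vm, Pm, Tm;
  IntegerVector Lv;
  NumericVector trial_ll;
  if (trace) {
    Qm = NumericMatrix(nt, n_bandits);
    Vm = NumericMatrix(nt, n_bandits);
    Pm = NumericMatrix(nt, n_bandits);
    Tm = NumericMatrix(nt, n_bandits);
    Lv = IntegerVector(nt);
    trial_ll = NumericVector(nt);
  }

  std::vector<double> logits(n_bandits), p(n_bandits);
  for (int t = 0; t < nt; ++t) {
    double mx = -HUGE_VAL;
    for (int i = 0; i < n_bandits; ++i) {
      double l = beta * Q[i];
      if (use_explore) {
        double u = (learning == 1)
          ? (bonus_type == 0 ? std::sqrt(V[i]) : V[i])
          : tsc[i];
        l += phi * u;
      }
      if (use_persev && i == last) l += rho;
      logits[i] = l;
      if (l > mx) mx = l;
    }
    double denom = 0.0;
    for (int i = 0; i < n_bandits; ++i) {
      p[i] = std::exp(logits[i] - mx);
      denom += p[i];
    }
    for (int i = 0; i < n_bandits; ++i) p[i] /= denom;

    if (trace) {
      for (int i = 0; i < n_bandits; ++i) {
        Qm(t, i) = Q[i];
        Vm(t, i) = V[i];
        Pm(t, i) = p[i];
        Tm(t, i) = tsc[i];
      }
      Lv[t] = (last < 0) ? NA_INTEGER : last + 1;
    }

    const bool mis = missed[t] != 0;
    if (!mis) {
      const int c = choice[t] - 1;
      if (c < 0 || c >= n_bandits) stop("choice index out of range");
      const double lp = std::log(p[c]);
      ll += lp;
      if (trace) trial_ll[t] = lp;
      const double out = outcome[t];
      if (learning == 0) {
        Q[c] += alpha * (out - Q[c]);
      } else {
        const double k = V[c] / (V[c] + obs_var);
        Q[c] += k * (out - Q[c]);
        V[c] *= (1.0 - k);
      }
      for (int i = 0; i < n_bandits; ++i) tsc[i] += 1.0;
      tsc[c] = 0.0;
      last = c;
    } else {
      if (trace) trial_ll[t] = 0.0;
      for (int i = 0; i < n_bandits; ++i) tsc[i] += 1.0;
    }

    if (learning == 1) {
      for (int i = 0; i < n_bandits; ++i) {
        Q[i] = decay * Q[i] + (1.0 - decay) * center;
        V[i] = decay * decay * V[i] + diff_var;
      }
    }
  }

  if (trace) {
    return List::create(_["log_lik"] = ll, _["values"] = Qm,
                        _["variances"] = Vm, _["probs"] = Pm,
                        _["trials_since"] = Tm, _["last_choice"] = Lv,
                        _["trial_log_lik"] = trial_ll);
  }
  return List::create(_["log_lik"] = ll);
}
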