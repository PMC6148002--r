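#include <Rcpp.h>
using namespace Rcpp;

// Branch-stable logistic: returns 1 / (1 + exp(x)) without overflowing for
// large |x|.
static inline double inv_logit_neg(double x) {
  if (x > 0.0) {
    double z = std::exp(-x);
    return z / (1.0 + z);
  }
  return 1.0 / (1.0 + std::exp(x));
}

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Synchronous coevolutionary Monte Carlo engine.
//
// Strategy coding: 1 = cooperator, 0 = defector.
// `payoff` is a 2x2 matrix indexed [focal + 1, opponent + 1] in this coding,
// i.e. payoff(0,0) = P(D,D), payoff(1,0) = P(C,D) of the cooperator, etc.
//
// RNG discipline (must match the pure-R reference step in dynamics.R):
// per step, first n uniforms choose the model neighbour of each player
// (j = neighbour floor(u * k_i)), then n uniforms decide adoption
// (adopt iff u < Prob_i). Uses R's RNG stream, so set.seed() upstream makes
// runs bit-reproducible.
//
// Step order (rep_before_adoption = false, the default):
//   1. accumulate payoffs from current strategies
//   2. pick a random model neighbour per player
//   3. synchronous adoption with probability
//      1 / (1 + exp((P_i - P_j)/(k_i K) - R_j)), all decisions read the
//      pre-step snapshot
//   4. reputation update from the strategies played in stage 1:
//      R_i <- clip(R_i +/- delta, -alpha, alpha)
// With rep_before_adoption = true, stage 4 runs before stage 3, so imitators
// see reputations that already include the current round's behaviour.
//
// Early stop: once strategies are homogeneous the composition is absorbing;
// observables are extended as constants and reputations are fast-forwarded
// analytically (every player keeps moving monotonically toward +/- alpha).
// [[Rcpp::export]]
List run_engine_cpp(IntegerVector nbr_flat,
                    IntegerVector offset,
                    IntegerVector degree,
                    IntegerVector strat0,
                    NumericVector rep0,
                    NumericMatrix payoff,
                    double delta,
                    double alpha,
                    double K,
                    int n_steps,
                    bool rep_before_adoption,
                    IntegerVector snapshot_steps,
                    bool early_stop) {
  const int n = strat0.size();
  std::vector<int> s(strat0.begin(), strat0.end());
  std::vector<int> s_new(n);
  std::vector<double> rep(rep0.begin(), rep0.end());
  std::vector<double> pay(n);
  std::vector<double> u1(n), u2(n);

  NumericVector rho_c(n_steps + 1);
  NumericVector rho_cc(n_steps + 1, NA_REAL);
  NumericVector rho_dd(n_steps + 1, NA_REAL);

  std::set<int> snap_at(snapshot_steps.begin(), snapshot_steps.end());
  List snapshots;
  CharacterVector snap_names;

  double pa[2][2];
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) pa[a][b] = payoff(a, b);

  int n_coop = 0;
  for (int i = 0; i < n; ++i) n_coop += s[i];
  rho_c[0] = (double)n_coop / n;
  if (snap_at.count(0)) {
    snapshots.push_back(IntegerVector(s.begin(), s.end()));
    snap_names.push_back("0");
  }

  int stopped_at = -1;

  for (int t = 1; t <= n_steps; ++t) {
    if (early_stop && (n_coop == 0 || n_coop == n)) {
      stopped_at = t - 1;
      break;
    }

    // stage 1: payoffs from current strategies
    for (int i = 0; i < n; ++i) {
      double p = 0.0;
      const int from = offset[i], to = offset[i + 1];
      for (int e = from; e < to; ++e) p += pa[s[i]][s[nbr_flat[e]]];
      pay[i] = p;
    }

    // uniforms: model choices first, then adoption draws
    for (int i = 0; i < n; ++i) u1[i] = unif_rand();
    for (int i = 0; i < n; ++i) u2[i] = unif_rand();

    if (rep_before_adoption) {
      for (int i = 0; i < n; ++i)
        rep[i] = clip(rep[i] + (s[i] == 1 ? delta : -delta), -alpha, alpha);
    }

    // stages 2-3: synchronous reputation-biased Fermi adoption
    int n_coop_new = 0, keep_c = 0, keep_d = 0;
    for (int i = 0; i < n; ++i) {
      const int k = degree[i];
      int idx = (int)(u1[i] * k);
      if (idx >= k) idx = k - 1;
      const int j = nbr_flat[offset[i] + idx];
      const double x = (pay[i] - pay[j]) / (k * K) - rep[j];
      const double prob = inv_logit_neg(x);
      s_new[i] = (u2[i] < prob) ? s[j] : s[i];
      n_coop_new += s_new[i];
      if (s[i] == 1 && s_new[i] == 1) ++keep_c;
      if (s[i] == 0 && s_new[i] == 0) ++keep_d;
    }

    // stage 4: reputation coevolution from the strategies just played
    if (!rep_before_adoption) {
      for (int i = 0; i < n; ++i)
        rep[i] = clip(rep[i] + (s[i] == 1 ? delta : -delta), -alpha, alpha);
    }

    rho_cc[t] = (n_coop > 0) ? (double)keep_c / n_coop : 0.0;
    rho_dd[t] = (n_coop < n) ? (double)keep_d / (n - n_coop) : 0.0;
    std::swap(s, s_new);
    n_coop = n_coop_new;
    rho_c[t] = (double)n_coop / n;

    if (snap_at.count(t)) {
      snapshots.push_back(IntegerVector(s.begin(), s.end()));
      snap_names.push_back(std::to_string(t));
    }
  }

  if (stopped_at >= 0) {
    // extend observables as the absorbing-state constants
    const double rc = rho_c[stopped_at];
    const double rcc = (n_coop == n) ? 1.0 : 0.0;
    const double rdd = (n_coop == 0) ? 1.0 : 0.0;
    for (int t = stopped_at + 1; t <= n_steps; ++t) {
      rho_c[t] = rc;
      rho_cc[t] = rcc;
      rho_dd[t] = rdd;
      if (snap_at.count(t)) {
        snapshots.push_back(IntegerVector(s.begin(), s.end()));
        snap_names.push_back(std::to_string(t));
      }
    }
    // fast-forward reputations: monotone drift to the saturation bound
    const int rem = n_steps - stopped_at;
    for (int i = 0; i < n; ++i)
      rep[i] = clip(rep[i] + (s[i] == 1 ? 1.0 : -1.0) * delta * rem,
                    -alpha, alpha);
  }

  snapshots.attr("names") = snap_names;
  return List::create(_["rho_c"] = rho_c,
                      _["rho_cc"] = rho_cc,
                      _["rho_dd"] = rho_dd,
                      _["final_strategies"] = IntegerVector(s.begin(), s.end()),
                      _["final_reputations"] = NumericVector(rep.begin(), rep.end()),
                      _["snapshots"] = snapshots,
                      _["stopped_at"] = stopped_at);
}

// Per-player total payoffs (compiled path used by the engine), exported for
// cross-checking against the vectorised R implementation.
// [[Rcpp::export]]
NumericVector accumulate_payoffs_cpp(IntegerVector nbr_flat,
                                     IntegerVector offset,
                                     IntegerVector strat,
                                     NumericMatrix payoff) {
  const int n = strat.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p = 0.0;
    for (int e = offset[i]; e < offset[i + 1]; ++e)
      p += payoff(strat[i], strat[nbr_flat[e]]);
    out[i] = p;
  }
  return out;
}
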