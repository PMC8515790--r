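#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of the phase-ring network for a finite
// ensemble of hexamer copies sharing one KaiA pool.
//
// Directed edges carry a first-order rate constant; edges flagged kaia are
// KaiA-binding events whose per-copy propensity is rate * round(freeA)/scale,
// where freeA = scale*A_T - (#P3 copies) - eps_seq * (#P2 copies) is the
// real-valued pool debit, clamped at zero.  Propensities are updated
// incrementally (only edges leaving the two touched nodes, plus the binding
// group when the free pool changes); the running total is refreshed
// periodically to control roundoff drift.  Uses R's RNG so set.seed() in R
// makes runs reproducible.
//
// [[Rcpp::export]]
NumericMatrix gillespie_core_cpp(int n_nodes,
                                 IntegerVector e_from,
                                 IntegerVector e_to,
                                 NumericVector e_rate,
                                 LogicalVector e_kaia,
                                 IntegerVector is_p3,
                                 IntegerVector is_p2,
                                 IntegerVector init_counts,
                                 double scale,
                                 double A_T,
                                 double eps_seq,
                                 NumericVector out_times) {
  const int n_e = e_from.size();
  const int n_out = out_times.size();
  std::vector<long> cnt(n_nodes);
  long n3 = 0, n2 = 0;
  for (int i = 0; i < n_nodes; ++i) {
    cnt[i] = init_counts[i];
    if (is_p3[i]) n3 += cnt[i];
    if (is_p2[i]) n2 += cnt[i];
  }
  // per-node outgoing edge lists and the binding-edge group
  std::vector<std::vector<int>> out_e(n_nodes);
  std::vector<int> kaia_e;
  for (int e = 0; e < n_e; ++e) {
    out_e[e_from[e]].push_back(e);
    if (e_kaia[e]) kaia_e.push_back(e);
  }

  NumericMatrix out(n_out, n_nodes);
  std::vector<double> a(n_e);

  auto freeA_factor = [&]() {
    double fa = std::round(scale * A_T - (double)n3 - eps_seq * (double)n2);
    if (fa < 0.0) fa = 0.0;
    return fa / scale;
  };

  double faf = freeA_factor();
  auto prop = [&](int e) {
    double r = e_rate[e];
    if (e_kaia[e]) r *= faf;
    return r * (double)cnt[e_from[e]];
  };

  double total = 0.0;
  for (int e = 0; e < n_e; ++e) { a[e] = prop(e); total += a[e]; }

  double t = 0.0;
  int out_idx = 0;
  const long refresh = 1L << 20;
  long max_events = 2000000000L;  // hard safety stop

  for (long ev = 0; ev < max_events; ++ev) {
    if ((ev & (refresh - 1)) == refresh - 1) {
      total = 0.0;
      for (int e = 0; e < n_e; ++e) total += a[e];
    }
    double tau = (total > 1e-300) ? R::exp_rand() / total : R_PosInf;
    double t_next = t + tau;
    while (out_idx < n_out && out_times[out_idx] <= t_next) {
      for (int i = 0; i < n_nodes; ++i) out(out_idx, i) = (double)cnt[i];
      ++out_idx;
    }
    if (out_idx >= n_out) break;
    if (!R_FINITE(t_next)) break;  // absorbing state before last output
    t = t_next;
    // pick the firing edge
    double u = unif_rand() * total;
    int e = 0;
    double acc = a[0];
    while (acc < u && e < n_e - 1) {
      ++e;
      acc += a[e];
    }
    if (cnt[e_from[e]] <= 0) continue;  // stale roundoff pick, skip
    int s = e_from[e], d = e_to[e];
    cnt[s] -= 1;
    cnt[d] += 1;
    long n3_old = n3, n2_old = n2;
    if (is_p3[s]) n3 -= 1;
    if (is_p3[d]) n3 += 1;
    if (is_p2[s]) n2 -= 1;
    if (is_p2[d]) n2 += 1;
    if (n3 != n3_old || n2 != n2_old) {
      double faf_new = freeA_factor();
      if (faf_new != faf) {
        faf = faf_new;
        for (int k : kaia_e) { total -= a[k]; a[k] = prop(k); total += a[k]; }
      }
    }
    for (int k : out_e[s]) { total -= a[k]; a[k] = prop(k); total += a[k]; }
    for (int k : out_e[d]) { total -= a[k]; a[k] = prop(k); total += a[k]; }
  }
  // pad remaining outputs with the final state (absorbing case)
  while (out_idx < n_out) {
    for (int i = 0; i < n_nodes; ++i) out(out_idx, i) = (double)cnt[i];
    ++out_idx;
  }
  return out;
}
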