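#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact direct-method SSA over one piecewise-constant segment [t0, t1] of
// the protocol (no events fire inside a segment; heat pulses are applied
// between segments in R, UV windows enter through `uv`).
//
// Species: I (inactive), A (active closed), O (active open) plus the
// multiset of chain lengths. Uses R's RNG so set.seed() in R governs
// reproducibility. f_uM is the concentration (uM) carried by one unit.
//
// record_times must be sorted ascending and lie within [t0, t1]; the
// state is snapshotted at each as soon as simulated time passes it.
// [[Rcpp::export]]
List ssa_segment_cpp(double t0, double t1,
                     double I, double A, double O,
                     IntegerVector chains0,
                     double f_uM,
                     List params,
                     double uv,
                     NumericVector record_times,
                     double max_events = 5e8) {
  const double k_open = as<double>(params["k_open"]);
  const double k_close = as<double>(params["k_close"]);
  const double k_nuc = as<double>(params["k_nuc"]);
  const double k_el = as<double>(params["k_el"]);
  const double k_join = as<double>(params["k_join"]);
  const double k_rf = as<double>(params["k_relax_free"]);
  const double k_rc = as<double>(params["k_relax_chain"]);

  std::vector<double> chains(chains0.begin(), chains0.end());
  double M = 0.0;  // total in-chain units
  for (double c : chains) M += c;

  double t = t0;
  double n_events = 0.0;
  R_xlen_t rec_i = 0;
  const R_xlen_t n_rec = record_times.size();
  List rec_out(n_rec);

  RNGScope scope;

  // snapshot helper
  auto snapshot = [&](double at) {
    IntegerVector ch(chains.size());
    for (size_t k = 0; k < chains.size(); ++k) ch[k] = (int)chains[k];
    return List::create(_["time"] = at, _["n_inactive"] = I,
                        _["n_active_closed"] = A, _["n_active_open"] = O,
                        _["chains"] = ch);
  };

  while (rec_i < n_rec && record_times[rec_i] <= t) {
    rec_out[rec_i] = snapshot(record_times[rec_i]);
    ++rec_i;
  }

  double a[7];
  for (;;) {
    const double C = (double)chains.size();
    a[0] = k_open * A;
    a[1] = k_close * O;
    a[2] = uv * k_rf * A;
    a[3] = k_nuc * f_uM * O * (O - 1.0);          // = 2 k f * O(O-1)/2
    a[4] = k_el * f_uM * C * O;
    a[5] = k_join * f_uM * C * (C - 1.0) * 0.5;
    a[6] = uv * k_rc * M;
    double a0 = 0.0;
    for (int k = 0; k < 7; ++k) a0 += a[k];

    double t_next;
    if (a0 <= 0.0) {
      t_next = t1 + 1.0;  // frozen: jump past the segment end
    } else {
      if (!R_FINITE(a0)) stop("propensity overflow/NaN in SSA (a0 not finite)");
      t_next = t + exp_rand() / a0;
    }

    if (t_next > t1) {
      while (rec_i < n_rec && record_times[rec_i] <= t1) {
        rec_out[rec_i] = snapshot(record_times[rec_i]);
        ++rec_i;
      }
      t = t1;
      break;
    }
    while (rec_i < n_rec && record_times[rec_i] < t_next) {
      rec_out[rec_i] = snapshot(record_times[rec_i]);
      ++rec_i;
    }
    t = t_next;

    double u = unif_rand() * a0;
    int c = 0;
    for (; c < 6; ++c) { if (u < a[c]) break; u -= a[c]; }

    switch (c) {
    case 0: A -= 1; O += 1; break;                       // open
    case 1: O -= 1; A += 1; break;                       // close
    case 2: A -= 1; I += 1; break;                       // relax_free
    case 3: O -= 2; chains.push_back(2.0); M += 2.0; break;  // nucleate
    case 4: {                                            // elongate
      size_t i = (size_t)(unif_rand() * chains.size());
      if (i >= chains.size()) i = chains.size() - 1;
      chains[i] += 1.0; O -= 1; M += 1.0;
      break;
    }
    case 5: {                                            // join
      size_t n = chains.size();
      size_t i = (size_t)(unif_rand() * n);
      if (i >= n) i = n - 1;
      size_t j = (size_t)(unif_rand() * (n - 1));
      if (j >= n - 1) j = n - 2;
      if (j >= i) ++j;
      chains[i] += chains[j];
      chains[j] = chains.back();
      chains.pop_back();
      break;
    }
    default: {                                           // relax_scission
      double w = unif_rand() * M, acc = 0.0;
      size_t i = 0;
      for (; i < chains.size(); ++i) {
        acc += chains[i];
        if (w < acc) break;
      }
      if (i >= chains.size()) i = chains.size() - 1;
      double n = chains[i];
      // relaxed subunit chosen uniformly over the chain
      double site = std::floor(unif_rand() * n) + 1.0;
      if (site > n) site = n;
      chains[i] = chains.back();
      chains.pop_back();
      M -= n;
      I += 1;  // the relaxed toroid leaves as inactive
      double frag[2] = { site - 1.0, n - site };
      for (int k = 0; k < 2; ++k) {
        if (frag[k] >= 2.0) { chains.push_back(frag[k]); M += frag[k]; }
        else if (frag[k] == 1.0) { O += 1; }
      }
      break;
    }
    }

    n_events += 1.0;
    if (n_events > max_events)
      stop("SSA event budget exceeded (%.0f events)", max_events);
  }

  IntegerVector ch(chains.size());
  for (size_t k = 0; k < chains.size(); ++k) ch[k] = (int)chains[k];
  return List::create(_["time"] = t, _["n_inactive"] = I,
                      _["n_active_closed"] = A, _["n_active_open"] = O,
                      _["chains"] = ch, _["event_count"] = n_events,
                      _["records"] = rec_out);
}

// Propensity vector of the seven channels on one state; exact image of
// the R network's propensities, used to cross-check the two engines.
// [[Rcpp::export]]
NumericVector ssa_propensities_cpp(double I, double A, double O,
                                   IntegerVector chains0, double f_uM,
                                   List params, double uv = 1.0) {
  const double k_open = as<double>(params["k_open"]);
  const double k_close = as<double>(params["k_close"]);
  const double k_nuc = as<double>(params["k_nuc"]);
  const double k_el = as<double>(params["k_el"]);
  const double k_join = as<double>(params["k_join"]);
  const double k_rf = as<double>(params["k_relax_free"]);
  const double k_rc = as<double>(params["k_relax_chain"]);
  double M = 0.0;
  for (int c : chains0) M += c;
  const double C = (double)chains0.size();
  NumericVector a(7);
  a[0] = k_open * A;
  a[1] = k_close * O;
  a[2] = uv * k_rf * A;
  a[3] = k_nuc * f_uM * O * (O - 1.0);
  a[4] = k_el * f_uM * C * O;
  a[5] = k_join * f_uM * C * (C - 1.0) * 0.5;
  a[6] = uv * k_rc * M;
  a.names() = CharacterVector::create("open", "close", "relax_free",
                                      "nucleate", "elongate", "join",
                                      "relax_scission");
  return a;
}
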