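// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Derivative of the length-resolved mean-field system.
// y = (I, A, O, c_2..c_nmax, leak_units), concentrations in uM.
// The joining gain is the discrete self-convolution of the chain-length
// distribution (padded FFT); scission uses tail sums.
//
// Truncation handling (`reflect`):
//   false ("leak"): elongation/joining flux past n_max drains into the
//     absorbing leak bin (exact image of the open system; the caller
//     enforces a leakage bound).
//   true ("reflect"): chains of length n_max do not elongate and pair
//     joins whose sum exceeds n_max are rejected, so total units are
//     conserved exactly at the cost of piling mass near the boundary;
//     used by the fitting objective where mass partition, not the far
//     tail, drives the observables.
// `qss`: treat the open-spiral pool as quasi-stationary,
// O* = k_open A / (k_close + k_el C_elig), folding its (<1%) mass into
// the closed pool. Removes the fastest modes (open/close interconversion
// and early per-chain elongation), so the optimizer's objective
// integrates with ~10x fewer steps; the full dynamics remain the
// default everywhere else.
// [[Rcpp::export]]
NumericVector meanfield_rhs_cpp(double t, NumericVector y, List params,
                                double uv, bool reflect = false,
                                bool qss = false) {
  const double k_open = as<double>(params["k_open"]);
  const double k_close = as<double>(params["k_close"]);
  const double k_nuc = as<double>(params["k_nuc"]);
  const double k_el = as<double>(params["k_el"]);
  const double k_join = as<double>(params["k_join"]);
  const double krf = uv * as<double>(params["k_relax_free"]);
  const double krc = uv * as<double>(params["k_relax_chain"]);

  const int m = y.size() - 4;          // chain bins, lengths 2..m+1
  const double A = y[1];
  double O = y[2];
  arma::vec cc(m);
  for (int i = 0; i < m; ++i) cc[i] = std::max(y[3 + i], 0.0);

  double Ctot = arma::accu(cc);
  double M = 0.0;
  for (int i = 0; i < m; ++i) M += (i + 2.0) * cc[i];

  // in reflect mode the boundary bin neither elongates nor consumes O
  const double Celig = reflect ? Ctot - cc[m - 1] : Ctot;

  NumericVector dy(y.size());
  dy[0] = krf * A + krc * M;                                   // inactive
  if (qss) {
    O = k_open * A / (k_close + k_el * Celig);
    dy[1] = -krf * A - 2.0 * k_nuc * O * O - k_el * O * Celig +
      2.0 * krc * Ctot;
    dy[2] = 0.0;  // open pool folded into the closed slot
  } else {
    dy[1] = -k_open * A + k_close * O - krf * A;               // active closed
    dy[2] = k_open * A - k_close * O - 2.0 * k_nuc * O * O -
      k_el * O * Celig + 2.0 * krc * Ctot;                     // active open
  }

  // elongation ladder + nucleation
  double leak = reflect ? 0.0 : k_el * O * cc[m - 1] * (m + 2.0);
  dy[3] = k_nuc * O * O - (m > 1 || !reflect ? k_el * O * cc[0] : 0.0);
  for (int i = 1; i < m - 1; ++i) {
    dy[3 + i] = k_el * O * (cc[i - 1] - cc[i]);
  }
  if (m >= 2) {
    dy[3 + m - 1] = reflect ? k_el * O * cc[m - 2]
                            : k_el * O * (cc[m - 2] - cc[m - 1]);
  }

  // scission: chain n destroyed at rate krc*n*c_n; fragments of each
  // length 0..n-1 produced at rate 2*krc*c_n
  double tail = 0.0;  // sum_{j > n} c_j, built from the top
  for (int i = m - 1; i >= 0; --i) {
    dy[3 + i] += -krc * (i + 2.0) * cc[i] + 2.0 * krc * tail;
    tail += cc[i];
  }

  if (k_join > 0.0 && Ctot > 0.0) {
    // self-convolution via power-of-two padded FFT:
    // s[t] = sum_{i+j=t} cc[i] cc[j], joined length = t + 4 (t 0-based)
    unsigned nfft = 1;
    while (nfft < 2 * (unsigned)m - 1) nfft <<= 1;
    arma::cx_vec F = arma::fft(cc, nfft);
    arma::vec sfull = arma::real(arma::ifft(F % F));
    arma::vec s = sfull.head(2 * m - 1);
    if (reflect) {
      // pair joins whose sum would exceed n_max are rejected: bin i may
      // only join partners j with (i+2) + (j+2) <= n_max = m+1
      arma::vec prefix = arma::cumsum(cc);
      for (int i = 0; i < m; ++i) {
        int jmax = m - i - 3;
        double allowed = (jmax >= 0) ? prefix[std::min(jmax, m - 1)] : 0.0;
        int tpos = i - 2;
        double gain = (tpos >= 0 && tpos < (int)s.n_elem) ?
          0.5 * s[tpos] : 0.0;
        if (gain < 0) gain = 0;
        dy[3 + i] += k_join * (gain - cc[i] * allowed);
      }
    } else {
      for (int i = 0; i < m; ++i) {
        int tpos = i - 2;              // joined length i+2 <- s index i-2
        double gain = (tpos >= 0 && tpos < (int)s.n_elem) ?
          0.5 * s[tpos] : 0.0;
        if (gain < 0) gain = 0;
        dy[3 + i] += k_join * (gain - cc[i] * Ctot);
      }
      // joined length tpos+4 exceeds n_max = m+1 once tpos >= m-2
      for (int tpos = m - 2; tpos < (int)s.n_elem; ++tpos) {
        leak += k_join * 0.5 * s[tpos] * (tpos + 4.0);
      }
    }
  }
  dy[3 + m] = leak;
  return dy;
}
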