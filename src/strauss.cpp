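#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-n single-point-displacement Metropolis-Hastings sampler for the
// Strauss density gamma^s(x). Coordinates are relative to the window origin
// (0..wx, 0..wy). Proposals: with probability 1/2 a fresh uniform location,
// otherwise a Gaussian jitter with sd jitter_sd; jitters are wrapped on a
// toroidal window and rejected outside a planar one. Acceptance ratio
// gamma^(s_new - s_old), with the gamma = 0 convention 0^0 = 1 (accept iff
// the move keeps s = 0). Pair closeness uses d < r*(1 - 1e-12) so lattice
// configurations at spacing exactly r count as s = 0 (see pair_count()).

static inline double pair_dist2(double dx, double dy, double wx, double wy,
                                bool toroidal) {
  dx = std::fabs(dx);
  dy = std::fabs(dy);
  if (toroidal) {
    if (dx > wx - dx) dx = wx - dx;
    if (dy > wy - dy) dy = wy - dy;
  }
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
List strauss_mh_cpp(NumericVector x0, NumericVector y0, double gamma,
                    double r, int n_sweeps, int burn_in, bool record_s,
                    double wx, double wy, bool toroidal, double jitter_sd) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  const double r2 = r * r * (1.0 - 1e-12);

  long s_tot = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (pair_dist2(x[i] - x[j], y[i] - y[j], wx, wy, toroidal) < r2)
        ++s_tot;

  const int n_rec = record_s ? (n_sweeps - burn_in) : 0;
  IntegerVector s_trace(n_rec);

  RNGScope scope;
  for (int it = 0; it < n_sweeps; ++it) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;

    double xn, yn;
    bool proposal_ok = true;
    if (unif_rand() < 0.5) {
      xn = unif_rand() * wx;
      yn = unif_rand() * wy;
    } else {
      xn = x[i] + norm_rand() * jitter_sd;
      yn = y[i] + norm_rand() * jitter_sd;
      if (toroidal) {
        // note: fmod is avoided deliberately (newer libm symbol); floor-based
        // wrapping is equivalent for these magnitudes
        xn -= wx * std::floor(xn / wx);
        yn -= wy * std::floor(yn / wy);
      } else if (xn < 0.0 || xn > wx || yn < 0.0 || yn > wy) {
        proposal_ok = false;  // target density is zero outside the window
      }
    }

    if (proposal_ok) {
      int s_old = 0, s_new = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (pair_dist2(x[i] - x[j], y[i] - y[j], wx, wy, toroidal) < r2)
          ++s_old;
        if (pair_dist2(xn - x[j], yn - y[j], wx, wy, toroidal) < r2)
          ++s_new;
      }
      const int ds = s_new - s_old;
      bool accept;
      if (gamma <= 0.0)
        accept = (s_new == 0);
      else if (ds <= 0)
        accept = true;
      else
        accept = (unif_rand() < std::pow(gamma, (double)ds));
      if (accept) {
        x[i] = xn;
        y[i] = yn;
        s_tot += ds;
      }
    }
    if (record_s && it >= burn_in) s_trace[it - burn_in] = (int)s_tot;
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["s_trace"] = s_trace,
                      _["s_final"] = (double)s_tot);
}
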