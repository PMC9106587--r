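#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Symmetric-normalization correlation estimator at integer lag k over the
// index range [lo, hi) of the traces:
//   G = [ (1/m) sum x_t y_{t+k} ] / [ mean(x head) mean(y tail) ] - 1
static double g_at(const std::vector<double> &x, const std::vector<double> &y,
                   long k, long lo, long hi) {
  const long m = hi - lo - k;
  if (m < 2) return NA_REAL;
  double num = 0, mx = 0, my = 0;
  const double *px = x.data() + lo, *py = y.data() + lo + k;
  for (long t = 0; t < m; ++t) {
    num += px[t] * py[t];
    mx += px[t];
    my += py[t];
  }
  mx /= m;
  my /= m;
  if (mx <= 0 || my <= 0) return NA_REAL;
  return (num / m) / (mx * my) - 1.0;
}

static void coarsen(std::vector<double> &x) {
  const size_t m = x.size() / 2;
  for (size_t i = 0; i < m; ++i) x[i] = x[2 * i] + x[2 * i + 1];
  x.resize(m);
}

// Multi-tau correlator on binned photon counts. `m` linear lags per octave,
// coarsening the trace by 2 per octave; the reported G is computed over the
// full trace, per-lag standard errors by block averaging over `nblocks`
// contiguous blocks of the (current-level) trace.
// [[Rcpp::export(name = ".multitau_cpp")]]
List multitau_cpp(NumericVector counts1, NumericVector counts2,
                  double bin_width, int m, double max_lag, int nblocks) {
  std::vector<double> x(counts1.begin(), counts1.end());
  std::vector<double> y(counts2.begin(), counts2.end());

  std::vector<double> lag_s, G, se;
  double w = bin_width;
  int level = 0;
  for (;;) {
    const long n = (long)x.size();
    if (n < 4 * m) break;
    const int k0 = (level == 0) ? 1 : m / 2 + 1;
    bool done = false;
    for (int k = k0; k <= m; ++k) {
      const double tau = k * w;
      if (tau > max_lag) { done = true; break; }
      lag_s.push_back(tau);
      G.push_back(g_at(x, y, k, 0, n));
      const long bl = n / nblocks;
      double sum = 0, sum2 = 0;
      int nb = 0;
      if (bl > 2 * k) {
        for (int b = 0; b < nblocks; ++b) {
          const double g = g_at(x, y, k, b * bl, (b + 1) * bl);
          if (R_finite(g)) { sum += g; sum2 += g * g; ++nb; }
        }
      }
      if (nb > 2) {
        const double var = (sum2 - sum * sum / nb) / (nb - 1);
        se.push_back(std::sqrt(std::max(var, 0.0) / nb));
      } else {
        se.push_back(NA_REAL);
      }
    }
    if (done) break;
    coarsen(x);
    coarsen(y);
    w *= 2;
    ++level;
  }

  return List::create(_["lag"] = lag_s, _["G"] = G, _["se"] = se);
}
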