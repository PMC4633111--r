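#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Gaussian KDE evaluated at x for a sorted sample with bandwidth h.
// Kernel support is truncated at 8 bandwidths (contribution < 1e-14,
// below the density floor), located by binary search.
static double kde_at(double x, const std::vector<double>& v, double h) {
  const double cut = 8.0 * h;
  std::vector<double>::const_iterator lo =
      std::lower_bound(v.begin(), v.end(), x - cut);
  std::vector<double>::const_iterator hi =
      std::upper_bound(v.begin(), v.end(), x + cut);
  double acc = 0.0;
  for (std::vector<double>::const_iterator it = lo; it != hi; ++it) {
    double z = (x - *it) / h;
    acc += std::exp(-0.5 * z * z);
  }
  const double inv_sqrt_2pi = 0.3989422804014327;
  return acc * inv_sqrt_2pi / (h * (double)v.size());
}

// Trapezoid integral on a uniform grid with spacing dx.
static double trapz_uniform(const std::vector<double>& y, double dx) {
  double s = 0.0;
  for (size_t k = 0; k < y.size(); ++k) s += y[k];
  s -= 0.5 * (y.front() + y.back());
  return s * dx;
}

// [[Rcpp::export(name = ".kls_matrix_cpp")]]
NumericMatrix kls_matrix_cpp(List samples, NumericVector bandwidth,
                             int n_grid, double floor_eps) {
  int R = samples.size();
  std::vector< std::vector<double> > v(R);
  std::vector<double> vmin(R), vmax(R);
  for (int i = 0; i < R; ++i) {
    NumericVector s = samples[i];
    v[i].assign(s.begin(), s.end());
    std::sort(v[i].begin(), v[i].end());
    vmin[i] = v[i].front();
    vmax[i] = v[i].back();
  }
  NumericMatrix out(R, R);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> p(n_grid), q(n_grid);
  for (int i = 0; i < R - 1; ++i) {
    for (int j = i + 1; j < R; ++j) {
      double hm = std::max(bandwidth[i], bandwidth[j]);
      double lo = std::min(vmin[i], vmin[j]) - 3.0 * hm;
      double hi = std::max(vmax[i], vmax[j]) + 3.0 * hm;
      double dx = (hi - lo) / (double)(n_grid - 1);
      for (int k = 0; k < n_grid; ++k) {
        double x = lo + dx * k;
        p[k] = std::max(kde_at(x, v[i], bandwidth[i]), floor_eps);
        q[k] = std::max(kde_at(x, v[j], bandwidth[j]), floor_eps);
      }
      double zp = trapz_uniform(p, dx), zq = trapz_uniform(q, dx);
      for (int k = 0; k < n_grid; ++k) { p[k] /= zp; q[k] /= zq; }
      std::vector<double> integrand(n_grid);
      for (int k = 0; k < n_grid; ++k) {
        double lr = std::log(p[k] / q[k]);
        integrand[k] = p[k] * lr - q[k] * lr;
      }
      double kl = trapz_uniform(integrand, dx);
      if (kl < 0.0) kl = 0.0;
      out(i, j) = out(j, i) = std::exp(-kl);
    }
  }
  return out;
}
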