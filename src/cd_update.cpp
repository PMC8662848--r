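#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double a, double l) {
  const double m = std::fabs(a) - l;
  return m > 0.0 ? (a > 0.0 ? m : -m) : 0.0;
}

// Gauss-Seidel coordinate sweeps for the network-smoothed soft-threshold
// update of the gene-side singular vector. The unit-sphere constraint is
// handled through a running scale c (the implied KKT multiplier eta + sigma
// equals c at a fixed point): each coordinate update stores
//   u_j <- S(z_j + sigma * W_j u, lambda) / c
// with the newest values of the unit-scale vector u used inside the sweep,
// and c is re-estimated from the vector norm at the end of every sweep.
// Fixed points satisfy c * u_j = S(z_j + sigma * W_j u, lambda) with
// ||u||_2 = 1, i.e. the stationarity conditions of the sphere-constrained
// subproblem, for every sigma. W is in compressed sparse column form
// (symmetric, zero diagonal). Sweeps stop when the normalized vector moves
// by less than tol in the sup norm.
// [[Rcpp::export]]
List cd_update_u(NumericVector z, IntegerVector w_p, IntegerVector w_i,
                 NumericVector w_x, double lambda, double sigma,
                 NumericVector u0, int max_sweeps, double tol) {
  const int p = z.size();
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> prev(p);
  const bool have_w = sigma > 0.0 && w_p.size() == p + 1;
  const double eps = 1e-300;

  // initial scale estimate from a Jacobi pass at u0
  double c = 0.0;
  for (int j = 0; j < p; ++j) {
    double a = z[j];
    if (have_w) {
      for (int k = w_p[j]; k < w_p[j + 1]; ++k)
        a += sigma * w_x[k] * u[w_i[k]];
    }
    const double r = soft(a, lambda);
    c += r * r;
  }
  c = std::sqrt(c);
  if (c < eps) c = 1.0;

  int sweeps = 0;
  bool converged = false;
  bool zeroed = false;
  for (int s = 0; s < max_sweeps; ++s) {
    ++sweeps;
    std::copy(u.begin(), u.end(), prev.begin());
    for (int j = 0; j < p; ++j) {
      double a = z[j];
      if (have_w) {
        for (int k = w_p[j]; k < w_p[j + 1]; ++k)
          a += sigma * w_x[k] * u[w_i[k]];
      }
      u[j] = soft(a, lambda) / c;
    }
    double nrm = 0.0;
    for (int j = 0; j < p; ++j) nrm += u[j] * u[j];
    nrm = std::sqrt(nrm);
    if (nrm < eps) {  // every coordinate thresholded to zero: degenerate
      zeroed = true;
      converged = true;
      break;
    }
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      u[j] /= nrm;
      delta = std::max(delta, std::fabs(u[j] - prev[j]));
    }
    c *= nrm;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  if (zeroed) std::fill(u.begin(), u.end(), 0.0);
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["scale"] = c);
}
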