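#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic-programming solver for the optimal monotone reparameterization
// between two SRVFs sampled on a common uniform grid.  The grid of
// (i, j) nodes is searched over a fixed set of coprime local steps whose
// slopes lie in [1/4, 4]; the local cost of a step approximates
// int q1(t) . q2(gamma(t)) sqrt(gamma'(t)) dt with linear interpolation
// of q2 between samples.  Ties are broken toward the diagonal step so a
// pair of identical inputs returns the identity warp.

static const int N_STEP = 11;
static const int STEP_A[N_STEP] = {1, 1, 2, 1, 3, 2, 3, 1, 4, 3, 4};
static const int STEP_B[N_STEP] = {1, 2, 1, 3, 1, 3, 2, 4, 1, 4, 3};

// [[Rcpp::export(name = ".dp_reparam_cpp")]]
List dp_reparam_cpp(NumericMatrix q1, NumericMatrix q2) {
  const int m = q1.nrow();
  if (q2.nrow() != m || q1.ncol() != 2 || q2.ncol() != 2)
    stop("q1 and q2 must be m x 2 matrices on the same grid");
  if (m < 4) stop("grid too small for reparameterization search");

  const double NEG = -1e30;
  const double dt = 1.0 / (m - 1);
  std::vector<double> E((size_t)m * m, NEG);
  std::vector<int> from((size_t)m * m, -1);
  E[0] = 0.0;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      double best = NEG;
      int barg = -1;
      for (int s = 0; s < N_STEP; ++s) {
        const int a = STEP_A[s], b = STEP_B[s];
        const int pi = i - a, pj = j - b;
        if (pi < 0 || pj < 0) continue;
        const double ev = E[(size_t)pi * m + pj];
        if (ev <= NEG / 2) continue;
        const double slope = (double)b / (double)a;
        const double sq = std::sqrt(slope);
        double c = 0.0;
        for (int k = 1; k <= a; ++k) {
          const double gj = pj + k * slope;
          int j0 = (int)std::floor(gj);
          if (j0 > m - 1) j0 = m - 1;
          double w = gj - j0;
          int j1 = j0 + 1;
          if (j1 > m - 1) { j1 = m - 1; w = 0.0; }
          const double qx = (1.0 - w) * q2(j0, 0) + w * q2(j1, 0);
          const double qy = (1.0 - w) * q2(j0, 1) + w * q2(j1, 1);
          c += q1(pi + k, 0) * qx + q1(pi + k, 1) * qy;
        }
        const double v = ev + c * sq * dt;
        if (v > best + 1e-14) { best = v; barg = s; }
      }
      E[(size_t)i * m + j] = best;
      from[(size_t)i * m + j] = barg;
    }
  }

  // backtrack the optimal lattice path into a warp gamma(i)
  NumericVector gamma(m);
  std::vector<double> gj(m, -1.0);
  int i = m - 1, j = m - 1;
  gj[i] = j;
  while (i > 0 || j > 0) {
    const int s = from[(size_t)i * m + j];
    if (s < 0) stop("no feasible reparameterization path");
    const int a = STEP_A[s], b = STEP_B[s];
    const double slope = (double)b / (double)a;
    for (int k = 1; k < a; ++k) gj[i - k] = j - k * slope;
    i -= a; j -= b;
    gj[i] = j;
  }
  // fill any grid rows skipped by multi-row steps (already interpolated
  // above for interior k); remaining -1 cannot occur but guard anyway
  for (int t = 0; t < m; ++t) {
    if (gj[t] < 0) gj[t] = gj[t > 0 ? t - 1 : 0];
    gamma[t] = gj[t] / (m - 1);
  }
  gamma[0] = 0.0;
  gamma[m - 1] = 1.0;

  return List::create(_["gamma"] = gamma, _["value"] = E[(size_t)m * m - 1]);
}
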