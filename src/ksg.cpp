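#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chebyshev (max-norm) distance between rows i and j of m.
static inline double cheb(const NumericMatrix &m, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < m.ncol(); ++c) {
    double v = std::fabs(m(i, c) - m(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Kraskov algorithm-1 mutual information between the row spaces of x and y,
// in nats.  Neighbour searches are brute force O(n^2); n here is at most a
// few thousand per call.
// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int K) {
  int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (K < 1 || K >= n) stop("K must be in [1, n - 1]");
  std::vector<double> dx(n), dy(n), dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double a = cheb(x, i, j);
      double b = cheb(y, i, j);
      dx[j] = a; dy[j] = b; dj[j] = std::max(a, b);
    }
    dj[i] = R_PosInf; // exclude self
    std::vector<double> tmp(dj);
    std::nth_element(tmp.begin(), tmp.begin() + (K - 1), tmp.end());
    double eps = tmp[K - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)K) + R::digamma((double)n) - acc / n;
}

// KSG transfer entropy, in nats.  yf: target future (n), yp: target past
// embedding (n x d_y), xp: source past embedding (n x d_x).  The joint
// space (yf, yp, xp) is searched with K neighbours under the max-norm and
// the K-th neighbour distance is projected onto the marginal spaces
// (yp), (yf, yp) and (yp, xp) for strict-inequality neighbour counts.
// [[Rcpp::export]]
double ksg_te_cpp(NumericVector yf, NumericMatrix yp, NumericMatrix xp,
                  int K) {
  int n = yf.size();
  if (yp.nrow() != n || xp.nrow() != n)
    stop("yf, yp, xp must have matching lengths");
  if (K < 1 || K >= n) stop("K must be in [1, n - 1]");
  std::vector<double> d_yp(n), d_ypf(n), d_ypx(n), dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double a = cheb(yp, i, j);
      double f = std::fabs(yf[i] - yf[j]);
      double s = cheb(xp, i, j);
      d_yp[j] = a;
      d_ypf[j] = std::max(a, f);
      d_ypx[j] = std::max(a, s);
      dj[j] = std::max(d_ypf[j], s);
    }
    dj[i] = R_PosInf;
    std::vector<double> tmp(dj);
    std::nth_element(tmp.begin(), tmp.begin() + (K - 1), tmp.end());
    double eps = tmp[K - 1];
    int n1 = 0, n2 = 0, n3 = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (d_yp[j] < eps) ++n1;
      if (d_ypf[j] < eps) ++n2;
      if (d_ypx[j] < eps) ++n3;
    }
    acc += R::digamma(n1 + 1.0) - R::digamma(n2 + 1.0) -
           R::digamma(n3 + 1.0);
  }
  return R::digamma((double)K) + acc / n;
}
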