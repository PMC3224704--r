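#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kernel-density mutual-information backend.
//
// All estimators operate on copula-transformed profiles (ranks scaled to
// (0,1)); the transform itself is done in R. The MI estimate at sample
// points x_i is mean_i log( f_xy(x_i,y_i) / (f_x(x_i) f_y(y_i)) ) with a
// Gaussian product kernel of common bandwidth h, clamped at zero.

static inline double gauss(double d, double inv2h2) {
  return std::exp(-d * d * inv2h2);
}

// Pairwise kernel matrix for one profile (n x n, symmetric, diagonal 1).
static void kernel_matrix(const NumericVector& u, double h, std::vector<double>& K) {
  const int n = u.size();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double k = gauss(u[i] - u[j], inv2h2);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
}

static double mi_from_kernels(const std::vector<double>& Kx,
                              const std::vector<double>& Ky, int n) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double fj = 0.0, fx = 0.0, fy = 0.0;
    const double* kx = &Kx[(size_t)i * n];
    const double* ky = &Ky[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      fj += kx[j] * ky[j];
      fx += kx[j];
      fy += ky[j];
    }
    acc += std::log((double)n * fj / (fx * fy));
  }
  double mi = acc / n;
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double cpp_mi_pair(NumericVector u, NumericVector v, double h) {
  const int n = u.size();
  std::vector<double> Kx((size_t)n * n), Ky((size_t)n * n);
  kernel_matrix(u, h, Kx);
  kernel_matrix(v, h, Ky);
  return mi_from_kernels(Kx, Ky, n);
}

// MI between every row of U indexed by ridx (regulators) and every row of U.
// U: m x n matrix of copula-transformed profiles. Returns r x m matrix.
// Regulator kernel matrices are cached; each target kernel is built once.
// [[Rcpp::export]]
NumericMatrix cpp_mi_matrix(NumericMatrix U, IntegerVector ridx, double h) {
  const int m = U.nrow(), n = U.ncol(), r = ridx.size();
  std::vector<std::vector<double> > Kreg(r);
  std::vector<std::vector<double> > freg(r);
  for (int a = 0; a < r; ++a) {
    NumericVector u = U(ridx[a] - 1, _);
    Kreg[a].resize((size_t)n * n);
    kernel_matrix(u, h, Kreg[a]);
    freg[a].resize(n);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double* kk = &Kreg[a][(size_t)i * n];
      for (int j = 0; j < n; ++j) s += kk[j];
      freg[a][i] = s;
    }
  }
  NumericMatrix out(r, m);
  std::vector<double> Kt((size_t)n * n);
  std::vector<double> ft(n);
  for (int t = 0; t < m; ++t) {
    NumericVector v = U(t, _);
    kernel_matrix(v, h, Kt);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double* kk = &Kt[(size_t)i * n];
      for (int j = 0; j < n; ++j) s += kk[j];
      ft[i] = s;
    }
    for (int a = 0; a < r; ++a) {
      if (ridx[a] - 1 == t) { out(a, t) = NA_REAL; continue; }
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        double fj = 0.0;
        const double* kx = &Kreg[a][(size_t)i * n];
        const double* ky = &Kt[(size_t)i * n];
        for (int j = 0; j < n; ++j) fj += kx[j] * ky[j];
        acc += std::log((double)n * fj / (freg[a][i] * ft[i]));
      }
      double mi = acc / n;
      out(a, t) = mi > 0.0 ? mi : 0.0;
    }
  }
  return out;
}

// Null MI sample: for one pair of profiles (kernel matrices reused across
// permutations), compute MI after randomly permuting the pairing of v
// against u. Permutations use R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector cpp_mi_null(NumericVector u, NumericVector v, double h, int n_perm) {
  const int n = u.size();
  std::vector<double> Kx((size_t)n * n), Ky((size_t)n * n);
  kernel_matrix(u, h, Kx);
  kernel_matrix(v, h, Ky);
  std::vector<double> fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    double sx = 0.0, sy = 0.0;
    for (int j = 0; j < n; ++j) {
      sx += Kx[(size_t)i * n + j];
      sy += Ky[(size_t)i * n + j];
    }
    fx[i] = sx;
    fy[i] = sy;
  }
  std::vector<int> p(n);
  NumericVector out(n_perm);
  GetRNGstate();
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates with R RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double fj = 0.0;
      const double* kx = &Kx[(size_t)i * n];
      const double* ky = &Ky[(size_t)p[i] * n];
      for (int j = 0; j < n; ++j) fj += kx[j] * ky[p[j]];
      acc += std::log((double)n * fj / (fx[i] * fy[p[i]]));
    }
    double mi = acc / n;
    out[b] = mi > 0.0 ? mi : 0.0;
  }
  PutRNGstate();
  return out;
}
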