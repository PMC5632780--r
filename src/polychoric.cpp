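// Two-step polychoric estimation: standard bivariate normal rectangle
// probabilities and the profile likelihood in rho, maximised per pair.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 48-point Gauss-Legendre nodes/weights on [-1, 1], built once by Newton
// iteration on the Legendre recurrence.
static std::vector<double> gl_x, gl_w;

static void gl_init(int m = 48) {
  if (!gl_x.empty()) return;
  gl_x.resize(m); gl_w.resize(m);
  for (int i = 0; i < m; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (m + 0.5));
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < m; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      double dp = m * (x * p0 - p1) / (x * x - 1.0);
      double x1 = x; x = x1 - p0 / dp;
      if (std::fabs(x - x1) < 1e-15) break;
    }
    double p0 = 1.0, p1 = 0.0;
    for (int j = 0; j < m; ++j) {
      double p2 = p1; p1 = p0;
      p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
    }
    double dp = m * (x * p0 - p1) / (x * x - 1.0);
    gl_x[i] = x;
    gl_w[i] = 2.0 / ((1.0 - x * x) * dp * dp);
  }
}

// P(X <= h, Y <= k) for standard bivariate normal with correlation r.
// Uses Phi(h)Phi(k) + integral_0^r of the bivariate density in rho
// (Plackett's identity), integrated by fixed Gauss-Legendre quadrature.
static double pbvnorm(double h, double k, double r) {
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  if (h == R_PosInf) return (k == R_PosInf) ? 1.0 : R::pnorm(k, 0.0, 1.0, 1, 0);
  if (k == R_PosInf) return R::pnorm(h, 0.0, 1.0, 1, 0);
  double p = R::pnorm(h, 0.0, 1.0, 1, 0) * R::pnorm(k, 0.0, 1.0, 1, 0);
  if (r == 0.0) return p;
  gl_init();
  const double c = r / 2.0;
  double s = 0.0;
  for (size_t i = 0; i < gl_x.size(); ++i) {
    double t = c * (gl_x[i] + 1.0);          // maps [-1,1] -> [0, r]
    double o = 1.0 - t * t;
    s += gl_w[i] * std::exp(-(h * h - 2.0 * t * h * k + k * k) / (2.0 * o)) /
         std::sqrt(o);
  }
  p += s * c / (2.0 * M_PI);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".pbvnormCpp")]]
double pbvnorm_cpp(double h, double k, double r) { return pbvnorm(h, k, r); }

// Profile log-likelihood sum n_ij log pi_ij(rho); cuts are the finite inner
// cut-points, extended to +/-Inf boundaries here. Cells with zero expected
// mass are floored at 1e-12 (only reachable with zero observed count under
// valid thresholds, so the floor never distorts the maximiser).
static double poly_loglik(const IntegerMatrix &tab,
                          const std::vector<double> &ca,
                          const std::vector<double> &cb, double rho) {
  const int La = tab.nrow(), Lb = tab.ncol();
  std::vector<double> grid((La + 1) * (Lb + 1));
  for (int i = 0; i <= La; ++i) {
    double a = (i == 0) ? R_NegInf : (i == La ? R_PosInf : ca[i - 1]);
    for (int j = 0; j <= Lb; ++j) {
      double b = (j == 0) ? R_NegInf : (j == Lb ? R_PosInf : cb[j - 1]);
      grid[i * (Lb + 1) + j] = pbvnorm(a, b, rho);
    }
  }
  double ll = 0.0;
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      int n = tab(i, j);
      if (n == 0) continue;
      double pi = grid[(i + 1) * (Lb + 1) + (j + 1)] -
                  grid[i * (Lb + 1) + (j + 1)] -
                  grid[(i + 1) * (Lb + 1) + j] + grid[i * (Lb + 1) + j];
      if (pi < 1e-12) pi = 1e-12;
      ll += n * std::log(pi);
    }
  return ll;
}

// [[Rcpp::export(name = ".polyLoglikCpp")]]
double poly_loglik_cpp(IntegerMatrix tab, NumericVector cutsA,
                       NumericVector cutsB, double rho) {
  std::vector<double> ca(cutsA.begin(), cutsA.end());
  std::vector<double> cb(cutsB.begin(), cutsB.end());
  return poly_loglik(tab, ca, cb, rho);
}

// Maximise the profile likelihood over rho in [-0.999, 0.999]: coarse scan
// then golden-section refinement (the profile is unimodal in practice; the
// scan guards against a bad bracket).
static double poly_fit(const IntegerMatrix &tab, const std::vector<double> &ca,
                       const std::vector<double> &cb) {
  const double lo = -0.999, hi = 0.999;
  double best_r = 0.0, best_ll = -HUGE_VAL;
  for (int g = 0; g <= 40; ++g) {
    double r = lo + (hi - lo) * g / 40.0;
    double ll = poly_loglik(tab, ca, cb, r);
    if (ll > best_ll) { best_ll = ll; best_r = r; }
  }
  double a = std::max(lo, best_r - (hi - lo) / 40.0);
  double b = std::min(hi, best_r + (hi - lo) / 40.0);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = poly_loglik(tab, ca, cb, x1), f2 = poly_loglik(tab, ca, cb, x2);
  while (b - a > 1e-7) {
    if (f1 < f2) { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a);
                   f2 = poly_loglik(tab, ca, cb, x2); }
    else         { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a);
                   f1 = poly_loglik(tab, ca, cb, x1); }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export(name = ".polyFitCpp")]]
double poly_fit_cpp(IntegerMatrix tab, NumericVector cutsA, NumericVector cutsB) {
  std::vector<double> ca(cutsA.begin(), cutsA.end());
  std::vector<double> cb(cutsB.begin(), cutsB.end());
  return poly_fit(tab, ca, cb);
}

// Full pairwise polychoric matrix. data holds codes 0..L-1 with NA for
// missing. Thresholds come from each pair's own margins (two-step profile
// estimation on pairwise-complete rows). Returns rho, per-pair n, and a
// degenerate-margin flag per pair (caller decides how to error).
// [[Rcpp::export(name = ".polyMatrixCpp")]]
List poly_matrix_cpp(IntegerMatrix data, int L) {
  const int n = data.nrow(), p = data.ncol();
  NumericMatrix rho(p, p), pairn(p, p);
  LogicalMatrix degen(p, p);
  for (int i = 0; i < p; ++i) { rho(i, i) = 1.0; pairn(i, i) = 0; }
  for (int i = 0; i < p; ++i) pairn(i, i) = 0;
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      IntegerMatrix tab(L, L);
      int m = 0;
      for (int r = 0; r < n; ++r) {
        int x = data(r, a), y = data(r, b);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        tab(x, y)++; m++;
      }
      pairn(a, b) = pairn(b, a) = m;
      // margins and thresholds
      std::vector<double> ma(L, 0.0), mb(L, 0.0);
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) { ma[i] += tab(i, j); mb[j] += tab(i, j); }
      int nza = 0, nzb = 0;
      for (int i = 0; i < L; ++i) { if (ma[i] > 0) nza++; if (mb[i] > 0) nzb++; }
      if (m < 2 || nza < 2 || nzb < 2) {
        degen(a, b) = degen(b, a) = true;
        rho(a, b) = rho(b, a) = NA_REAL;
        continue;
      }
      std::vector<double> ca(L - 1), cb(L - 1);
      double cum = 0.0;
      for (int i = 0; i < L - 1; ++i) {
        cum += ma[i];
        ca[i] = R::qnorm(cum / m, 0.0, 1.0, 1, 0);
      }
      cum = 0.0;
      for (int j = 0; j < L - 1; ++j) {
        cum += mb[j];
        cb[j] = R::qnorm(cum / m, 0.0, 1.0, 1, 0);
      }
      double r = poly_fit(tab, ca, cb);
      rho(a, b) = rho(b, a) = r;
    }
  }
  return List::create(_["rho"] = rho, _["pair_n"] = pairn,
                      _["degenerate"] = degen);
}
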