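// Score-based DAG search: linear-Gaussian BIC (higher is better), greedy
// best-move hill climbing over add/delete/reverse with acyclicity checks,
// random restarts by perturbation. Family scores are computed from the MLE
// covariance matrix and memoised per (node, parent-set) so bootstrap loops
// stay cheap. Randomness comes from R's RNG stream.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Scorer {
  const arma::mat &C;   // MLE covariance of the data
  double n;
  std::unordered_map<uint64_t, double> cache;
  Scorer(const arma::mat &C_, double n_) : C(C_), n(n_) {}
  // log-likelihood of node i given parents (bitmask), minus (k/2) log n,
  // k = |parents| + 2 (coefficients + intercept + residual variance)
  double fam(int i, uint32_t mask) {
    uint64_t key = (uint64_t(i) << 32) | mask;
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    double s2;
    int np = 0;
    arma::uvec pa(32);
    for (int b = 0; b < 32; ++b) if (mask & (1u << b)) pa[np++] = b;
    if (np == 0) {
      s2 = C(i, i);
    } else {
      arma::uvec P = pa.head(np);
      arma::mat Cpp = C.submat(P, P);
      arma::vec cip(np);
      for (int k = 0; k < np; ++k) cip[k] = C(i, P[k]);
      arma::vec sol;
      bool ok = arma::solve(sol, Cpp, cip, arma::solve_opts::no_approx);
      if (!ok) { cache[key] = NA_REAL; return NA_REAL; }
      s2 = C(i, i) - arma::dot(cip, sol);
    }
    double val;
    if (s2 < 1e-12) val = NA_REAL;
    else val = -0.5 * n * (std::log(2.0 * M_PI * s2) + 1.0) -
               0.5 * (np + 2) * std::log(n);
    cache[key] = val;
    return val;
  }
};

// does `to` become reachable from `from` following directed edges?
static bool reaches(int from, int to, const std::vector<uint32_t> &pa, int p) {
  if (from == to) return true;
  std::vector<char> seen(p, 0);
  std::vector<int> stack{from};
  seen[from] = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int c = 0; c < p; ++c) {
      if (!seen[c] && (pa[c] & (1u << u))) {
        if (c == to) return true;
        seen[c] = 1;
        stack.push_back(c);
      }
    }
  }
  return false;
}

struct Move { int type; int i; int j; double delta; }; // 0 add, 1 del, 2 rev

static double graph_score(const std::vector<uint32_t> &pa, Scorer &sc) {
  double s = 0.0;
  for (size_t i = 0; i < pa.size(); ++i) {
    double f = sc.fam(i, pa[i]);
    if (!std::isfinite(f)) return NA_REAL;
    s += f;
  }
  return s;
}

// enumerate valid moves in fixed lexicographic order; delta is NA when the
// family score is singular
static std::vector<Move> valid_moves(const std::vector<uint32_t> &pa, int p,
                                     Scorer &sc, bool with_delta) {
  std::vector<Move> out;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) {
      if (i == j) continue;
      bool eij = (pa[j] >> i) & 1u;
      if (!eij) {
        bool eji = (pa[i] >> j) & 1u;
        if (eji) continue;              // covered by reverse of (j, i)
        if (reaches(j, i, pa, p)) continue;   // add would close a cycle
        Move m{0, i, j, 0.0};
        if (with_delta)
          m.delta = sc.fam(j, pa[j] | (1u << i)) - sc.fam(j, pa[j]);
        out.push_back(m);
      } else {
        Move d{1, i, j, 0.0};
        if (with_delta)
          d.delta = sc.fam(j, pa[j] & ~(1u << i)) - sc.fam(j, pa[j]);
        out.push_back(d);
        // reverse i->j into j->i
        std::vector<uint32_t> tmp = pa;
        tmp[j] &= ~(1u << i);
        if (!reaches(i, j, tmp, p)) {
          Move r{2, i, j, 0.0};
          if (with_delta)
            r.delta = (sc.fam(j, pa[j] & ~(1u << i)) - sc.fam(j, pa[j])) +
                      (sc.fam(i, pa[i] | (1u << j)) - sc.fam(i, pa[i]));
          out.push_back(r);
        }
      }
    }
  return out;
}

static void apply_move(std::vector<uint32_t> &pa, const Move &m) {
  if (m.type == 0) pa[m.j] |= (1u << m.i);
  else if (m.type == 1) pa[m.j] &= ~(1u << m.i);
  else { pa[m.j] &= ~(1u << m.i); pa[m.i] |= (1u << m.j); }
}

static void climb(std::vector<uint32_t> &pa, int p, Scorer &sc) {
  const double eps = 1e-10;
  for (;;) {
    std::vector<Move> mv = valid_moves(pa, p, sc, true);
    int best = -1;
    double bd = eps;
    for (size_t k = 0; k < mv.size(); ++k) {
      if (!std::isfinite(mv[k].delta)) continue;
      if (mv[k].delta > bd) { bd = mv[k].delta; best = (int)k; }
    }
    if (best < 0) break;
    apply_move(pa, mv[best]);
  }
}

// [[Rcpp::export(name = ".hillClimbCpp")]]
List hill_climb_cpp(arma::mat X, int restarts, int perturbs) {
  const int n = X.n_rows, p = X.n_cols;
  if (p > 31) stop("at most 31 variables supported");
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  arma::mat C = (Xc.t() * Xc) / double(n);
  Scorer sc(C, double(n));
  std::vector<uint32_t> pa(p, 0u);
  climb(pa, p, sc);
  std::vector<uint32_t> best = pa;
  double best_s = graph_score(best, sc);
  if (!std::isfinite(best_s)) stop("singular family in hill climb");
  GetRNGstate();
  for (int r = 0; r < restarts; ++r) {
    std::vector<uint32_t> cur = best;
    for (int t = 0; t < perturbs; ++t) {
      std::vector<Move> mv = valid_moves(cur, p, sc, false);
      if (mv.empty()) break;
      int k = (int)std::floor(unif_rand() * mv.size());
      if (k >= (int)mv.size()) k = (int)mv.size() - 1;
      apply_move(cur, mv[k]);
    }
    climb(cur, p, sc);
    double s = graph_score(cur, sc);
    if (std::isfinite(s) && s > best_s + 1e-10) { best = cur; best_s = s; }
  }
  PutRNGstate();
  IntegerMatrix adj(p, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      adj(i, j) = (best[j] >> i) & 1u;
  return List::create(_["adjacency"] = adj, _["score"] = best_s);
}

// [[Rcpp::export(name = ".bicScoreCpp")]]
double bic_score_cpp(IntegerMatrix adj, arma::mat X) {
  const int n = X.n_rows, p = X.n_cols;
  if (adj.nrow() != p || adj.ncol() != p) stop("adjacency/data dimension mismatch");
  if (p > 31) stop("at most 31 variables supported");
  std::vector<uint32_t> pa(p, 0u);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (adj(i, j)) pa[j] |= (1u << i);
  // cycle check: Kahn's algorithm
  {
    std::vector<int> indeg(p, 0);
    for (int j = 0; j < p; ++j) {
      uint32_t m = pa[j];
      while (m) { indeg[j]++; m &= m - 1; }
    }
    std::vector<int> q;
    for (int j = 0; j < p; ++j) if (indeg[j] == 0) q.push_back(j);
    int seen = 0;
    while (!q.empty()) {
      int u = q.back(); q.pop_back(); seen++;
      for (int c = 0; c < p; ++c)
        if (pa[c] & (1u << u)) { if (--indeg[c] == 0) q.push_back(c); }
    }
    if (seen < p) stop("graph contains a cycle");
  }
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - mu;
  arma::mat C = (Xc.t() * Xc) / double(n);
  Scorer sc(C, double(n));
  double s = graph_score(pa, sc);
  if (!std::isfinite(s)) stop("singular parent design in BIC score");
  return s;
}
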