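// Dense two-phase primal simplex for box-constrained linear programs
//
//   min/max  c'x   s.t.  A x = b,   lb <= x <= ub   (finite bounds)
//
// Sized for small metabolic models (tens of reactions); the flux-bound
// evolutionary algorithm performs ~1e5 solves per run, which rules out a
// pure-R tableau.  Variables are shifted to y = x - lb; upper bounds become
// explicit slack rows, so the core loop is the textbook tableau method with
// artificial variables on the equality rows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double PIV_TOL = 1e-9;
static const double RC_TOL = 1e-9;
static const double FEAS_TOL = 1e-7;

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericVector cobj, NumericMatrix A, NumericVector b,
                  NumericVector lb, NumericVector ub, bool maximize) {
  const int n = A.ncol();
  const int m = A.nrow();

  // shift out fixed variables (lb == ub) entirely
  std::vector<int> freev;
  freev.reserve(n);
  std::vector<double> d(n);
  for (int j = 0; j < n; ++j) {
    d[j] = ub[j] - lb[j];
    if (d[j] < 0) stop("lower bound exceeds upper bound at column %d", j + 1);
    if (d[j] > PIV_TOL) freev.push_back(j);
  }
  const int nf = (int)freev.size();

  // b~ = b - A * lb
  std::vector<double> bt(m);
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int j = 0; j < n; ++j) s -= A(i, j) * lb[j];
    bt[i] = s;
  }

  // tableau: rows 0..m-1 equality, rows m..m+nf-1 upper-bound rows
  // cols: 0..nf-1 y, nf..2nf-1 slack, 2nf..2nf+m-1 artificial
  const int nrow = m + nf;
  const int ncol = 2 * nf + m;
  std::vector<std::vector<double>> T(nrow, std::vector<double>(ncol, 0.0));
  std::vector<double> rhs(nrow);
  std::vector<int> basis(nrow);

  for (int i = 0; i < m; ++i) {
    double sgn = (bt[i] < 0) ? -1.0 : 1.0;
    for (int k = 0; k < nf; ++k) T[i][k] = sgn * A(i, freev[k]);
    T[i][2 * nf + i] = 1.0;
    rhs[i] = sgn * bt[i];
    basis[i] = 2 * nf + i;
  }
  for (int k = 0; k < nf; ++k) {
    T[m + k][k] = 1.0;
    T[m + k][nf + k] = 1.0;
    rhs[m + k] = d[freev[k]];
    basis[m + k] = nf + k;
  }

  std::vector<double> cost(ncol, 0.0);
  std::vector<bool> allowed(ncol, true);
  std::vector<double> red(ncol);
  double iterbland = 200.0 + 10.0 * nrow;
  long iter = 0, maxiter = 200000;

  // one simplex phase on the current tableau; returns exit code
  auto run_phase = [&](void) -> int {
    for (;;) {
      if (++iter > maxiter) return 3;
      // reduced costs recomputed from scratch each iteration: O(nrow*ncol),
      // same order as the pivot update, and immune to incremental drift
      for (int j = 0; j < ncol; ++j) {
        double s = cost[j];
        for (int i = 0; i < nrow; ++i)
          if (cost[basis[i]] != 0.0) s -= cost[basis[i]] * T[i][j];
        red[j] = s;
      }
      bool bland = iter > iterbland;
      int ent = -1;
      double best = -RC_TOL;
      for (int j = 0; j < ncol; ++j) {
        if (!allowed[j]) continue;
        bool isbasic = false; // basic columns have reduced cost 0 anyway
        if (red[j] < -RC_TOL) {
          if (bland) { ent = j; break; }
          if (red[j] < best) { best = red[j]; ent = j; }
        }
        (void)isbasic;
      }
      if (ent < 0) return 0; // optimal for this phase
      // ratio test; rows holding a zero-valued artificial block at ratio 0
      int lv = -1;
      double bratio = std::numeric_limits<double>::infinity();
      for (int i = 0; i < nrow; ++i) {
        double a = T[i][ent];
        bool art = basis[i] >= 2 * nf;
        if (art && std::fabs(a) > PIV_TOL && rhs[i] <= FEAS_TOL) {
          if (0.0 < bratio - PIV_TOL ||
              (std::fabs(bratio) <= PIV_TOL && (lv < 0 || basis[i] < basis[lv]))) {
            bratio = 0.0; lv = i;
          }
          continue;
        }
        if (a > PIV_TOL) {
          double r = rhs[i] / a;
          if (r < bratio - PIV_TOL ||
              (std::fabs(r - bratio) <= PIV_TOL && (lv < 0 || basis[i] < basis[lv]))) {
            bratio = r; lv = i;
          }
        }
      }
      if (lv < 0) return 2; // unbounded direction
      // pivot on (lv, ent)
      double p = T[lv][ent];
      for (int j = 0; j < ncol; ++j) T[lv][j] /= p;
      rhs[lv] /= p;
      for (int i = 0; i < nrow; ++i) {
        if (i == lv) continue;
        double f = T[i][ent];
        if (std::fabs(f) < PIV_TOL) continue;
        for (int j = 0; j < ncol; ++j) T[i][j] -= f * T[lv][j];
        rhs[i] -= f * rhs[lv];
        if (rhs[i] < 0 && rhs[i] > -1e-11) rhs[i] = 0;
      }
      basis[lv] = ent;
    }
  };

  // phase 1: minimize artificial sum
  for (int i = 0; i < m; ++i) cost[2 * nf + i] = 1.0;
  int code = run_phase();
  if (code != 0) return List::create(_["status"] = code, _["x"] = R_NilValue,
                                     _["objective"] = NA_REAL);
  double art = 0.0;
  for (int i = 0; i < nrow; ++i)
    if (basis[i] >= 2 * nf) art += rhs[i];
  if (art > FEAS_TOL)
    return List::create(_["status"] = 1, _["x"] = R_NilValue,
                        _["objective"] = NA_REAL);

  // phase 2: real objective on y; artificials barred from re-entering
  double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < ncol; ++j) cost[j] = 0.0;
  for (int k = 0; k < nf; ++k) cost[k] = sgn * cobj[freev[k]];
  for (int j = 2 * nf; j < ncol; ++j) allowed[j] = false;
  iter = 0;
  code = run_phase();
  if (code == 2 || code == 3)
    return List::create(_["status"] = code, _["x"] = R_NilValue,
                        _["objective"] = NA_REAL);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = lb[j];
  for (int i = 0; i < nrow; ++i)
    if (basis[i] < nf) x[freev[basis[i]]] = lb[freev[basis[i]]] + rhs[i];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cobj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}
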