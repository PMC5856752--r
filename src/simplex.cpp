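#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex for
//     min c'x   subject to   A x <= b,  x >= 0,
// with b of arbitrary sign.  Rows with negative right-hand side are negated
// and given an artificial variable; phase 1 drives the artificials to zero,
// phase 2 optimizes c.  Entering column: Dantzig rule, switching permanently
// to Bland's rule after a long degenerate stall (guarantees termination).
//
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

namespace {

struct Tableau {
  int m, ncol;                  // rows, total columns (excluding rhs)
  std::vector<double> T;        // m x (ncol + 1), row-major; last col = rhs
  std::vector<int> basis;       // basis[i] = column basic in row i

  double &at(int i, int j) { return T[(size_t)i * (ncol + 1) + j]; }
  double rhs(int i) { return at(i, ncol); }

  void pivot(int pr, int pc) {
    const double piv = at(pr, pc);
    const double inv = 1.0 / piv;
    for (int j = 0; j <= ncol; ++j) at(pr, j) *= inv;
    at(pr, pc) = 1.0;
    for (int i = 0; i < m; ++i) {
      if (i == pr) continue;
      const double f = at(i, pc);
      if (f == 0.0) continue;
      double *ri = &T[(size_t)i * (ncol + 1)];
      const double *rp = &T[(size_t)pr * (ncol + 1)];
      for (int j = 0; j <= ncol; ++j) ri[j] -= f * rp[j];
      at(i, pc) = 0.0;
    }
    basis[pr] = pc;
  }
};

// reduced cost row for cost vector `cost` (length ncol) given current basis
void reduced_costs(Tableau &tb, const std::vector<double> &cost,
                   std::vector<double> &d, double &z) {
  d.assign(tb.ncol, 0.0);
  z = 0.0;
  std::vector<double> cb(tb.m);
  for (int i = 0; i < tb.m; ++i) {
    cb[i] = cost[tb.basis[i]];
    z += cb[i] * tb.rhs(i);
  }
  for (int j = 0; j < tb.ncol; ++j) d[j] = cost[j];
  for (int i = 0; i < tb.m; ++i) {
    if (cb[i] == 0.0) continue;
    const double *ri = &tb.T[(size_t)i * (tb.ncol + 1)];
    for (int j = 0; j < tb.ncol; ++j) d[j] -= cb[i] * ri[j];
  }
}

// one simplex phase; returns 0 optimal, 2 unbounded, 3 maxit
int run_phase(Tableau &tb, const std::vector<double> &cost,
              const std::vector<bool> &allowed, double tol, int maxit,
              int &iter_used) {
  std::vector<double> d;
  double z;
  reduced_costs(tb, cost, d, z);
  bool bland = false;
  int stall = 0;
  const int stall_limit = 4 * tb.m + 50;

  for (int it = 0; it < maxit; ++it) {
    // entering column
    int pc = -1;
    if (!bland) {
      double best = -tol;
      for (int j = 0; j < tb.ncol; ++j)
        if (allowed[j] && d[j] < best) { best = d[j]; pc = j; }
    } else {
      for (int j = 0; j < tb.ncol; ++j)
        if (allowed[j] && d[j] < -tol) { pc = j; break; }
    }
    if (pc < 0) { iter_used = it; return 0; }  // optimal

    // ratio test (Bland-compatible tie-break on basis column index)
    int pr = -1;
    double best_ratio = 0.0;
    for (int i = 0; i < tb.m; ++i) {
      const double a = tb.at(i, pc);
      if (a > tol) {
        const double r = tb.rhs(i) / a;
        if (pr < 0 || r < best_ratio - 1e-12 ||
            (r < best_ratio + 1e-12 && tb.basis[i] < tb.basis[pr]))
          { pr = i; best_ratio = r; }
      }
    }
    if (pr < 0) { iter_used = it; return 2; }  // unbounded

    if (best_ratio < 1e-12) {
      if (++stall > stall_limit) bland = true;
    } else stall = 0;

    // pivot and update reduced-cost row
    const double dj = d[pc];
    tb.pivot(pr, pc);
    const double *rp = &tb.T[(size_t)pr * (tb.ncol + 1)];
    for (int j = 0; j < tb.ncol; ++j) d[j] -= dj * rp[j];
    d[pc] = 0.0;
  }
  iter_used = maxit;
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".lp_simplex")]]
List lp_simplex(NumericVector obj, NumericMatrix A, NumericVector rhs,
                double tol = 1e-9, int maxit = 0) {
  const int m = A.nrow(), n = A.ncol();
  if (obj.size() != n || rhs.size() != m)
    stop("inconsistent LP dimensions");
  if (maxit <= 0) maxit = 200 * (m + n) + 5000;

  int n_art = 0;
  for (int i = 0; i < m; ++i) if (rhs[i] < 0) ++n_art;

  Tableau tb;
  tb.m = m;
  tb.ncol = n + m + n_art;
  tb.T.assign((size_t)m * (tb.ncol + 1), 0.0);
  tb.basis.assign(m, -1);

  std::vector<bool> is_art(tb.ncol, false);
  int art = 0;
  for (int i = 0; i < m; ++i) {
    const double s = (rhs[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) tb.at(i, j) = s * A(i, j);
    tb.at(i, n + i) = s;          // slack
    tb.at(i, tb.ncol) = s * rhs[i];
    if (s < 0) {
      const int ac = n + m + art++;
      tb.at(i, ac) = 1.0;
      is_art[ac] = true;
      tb.basis[i] = ac;
    } else {
      tb.basis[i] = n + i;
    }
  }

  std::vector<bool> allow_all(tb.ncol, true);
  std::vector<bool> allow_noart(tb.ncol, true);
  for (int j = 0; j < tb.ncol; ++j) if (is_art[j]) allow_noart[j] = false;

  int status = 0, it1 = 0, it2 = 0;

  if (n_art > 0) {
    std::vector<double> cost1(tb.ncol, 0.0);
    for (int j = 0; j < tb.ncol; ++j) if (is_art[j]) cost1[j] = 1.0;
    status = run_phase(tb, cost1, allow_all, tol, maxit, it1);
    double phase1 = 0.0;
    for (int i = 0; i < m; ++i)
      if (is_art[tb.basis[i]]) phase1 += tb.rhs(i);
    if (status == 0 && phase1 > 1e-7) status = 1;  // infeasible
    if (status == 0) {
      // pivot lingering zero-level artificials out of the basis when possible
      for (int i = 0; i < m; ++i) {
        if (!is_art[tb.basis[i]]) continue;
        for (int j = 0; j < n + m; ++j) {
          if (std::fabs(tb.at(i, j)) > 1e-7) { tb.pivot(i, j); break; }
        }
      }
    }
  }

  if (status == 0) {
    std::vector<double> cost2(tb.ncol, 0.0);
    for (int j = 0; j < n; ++j) cost2[j] = obj[j];
    status = run_phase(tb, cost2, allow_noart, tol, maxit, it2);
    if (status == 2 && n_art == 0) status = 2;
  }

  NumericVector x(n, 0.0);
  double objective = NA_REAL;
  if (status == 0) {
    for (int i = 0; i < m; ++i)
      if (tb.basis[i] < n) x[tb.basis[i]] = tb.rhs(i);
    objective = 0.0;
    for (int j = 0; j < n; ++j) {
      if (x[j] < 0 && x[j] > -1e-9) x[j] = 0.0;  // clip tiny negatives
      objective += obj[j] * x[j];
    }
  }

  return List::create(_["x"] = x, _["objective"] = objective,
                      _["status"] = status,
                      _["iterations"] = it1 + it2);
}
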