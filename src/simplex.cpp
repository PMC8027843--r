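// Bounded-variable primal simplex for the package's integer programs.
//
// Solves  min c'x  s.t.  Ax = b,  lb <= x <= ub  with all bounds finite.
// Two-phase with artificial variables; full-tableau updates; Dantzig
// pricing with a permanent switch to Bland's rule after a run of
// degenerate pivots. Branch-and-bound lives in R (see R/solver.R); this
// file only provides the LP kernel, so it must be exact and robust on
// small, well-scaled instances rather than fast on large ones.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PIV_TOL = 1e-9;
static const double RED_TOL = 1e-7;
static const double FEAS_TOL = 1e-7;

struct SimplexState {
  arma::mat T;            // m x ncol tableau (B^{-1} A_full)
  arma::vec xB;           // values of basic variables
  arma::uvec basis;       // basic variable index per row
  std::vector<bool> at_upper;   // nonbasic rest position
  std::vector<bool> in_basis;
  arma::vec lb, ub;
  int m, ncol;
};

// One simplex phase: optimize cost over current state. Returns 0 on
// optimal, 2 on iteration limit.
static int simplex_phase(SimplexState &S, const arma::vec &cost, int max_iter) {
  const int m = S.m, ncol = S.ncol;
  bool bland = false;
  int degen_run = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    // reduced costs d = cost - T' cB
    arma::vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = cost[S.basis[i]];
    arma::vec d = cost - S.T.t() * cB;

    int enter = -1, dir = 0;
    double best = -RED_TOL;
    for (int j = 0; j < ncol; ++j) {
      if (S.in_basis[j]) continue;
      if (S.ub[j] - S.lb[j] < PIV_TOL) continue;  // fixed variable
      double viol = 0.0; int dj = 0;
      if (!S.at_upper[j] && d[j] < -RED_TOL) { viol = d[j]; dj = +1; }
      else if (S.at_upper[j] && d[j] > RED_TOL) { viol = -d[j]; dj = -1; }
      else continue;
      if (bland) { enter = j; dir = dj; break; }
      if (viol < best) { best = viol; enter = j; dir = dj; }
    }
    if (enter < 0) return 0;  // optimal

    // ratio test
    double step = S.ub[enter] - S.lb[enter];  // bound-flip cap
    int leave_row = -1;
    double leave_coef = 0.0;
    for (int i = 0; i < m; ++i) {
      double coef = S.T(i, enter) * dir;  // xB[i] decreases by coef*step
      double lim = -1.0;
      if (coef > PIV_TOL) lim = (S.xB[i] - S.lb[S.basis[i]]) / coef;
      else if (coef < -PIV_TOL) lim = (S.xB[i] - S.ub[S.basis[i]]) / coef;
      else continue;
      if (lim < -1e-11) lim = 0.0;
      if (lim < step - 1e-12 ||
          (leave_row >= 0 && lim < step + 1e-12 &&
           S.basis[i] < S.basis[leave_row])) {
        if (lim <= step + 1e-12) { step = std::min(step, lim); leave_row = i; leave_coef = coef; }
      }
    }

    if (step < PIV_TOL) ++degen_run; else degen_run = 0;
    if (degen_run > 200) bland = true;

    if (leave_row < 0) {
      // entering variable flips to its other bound
      S.xB -= S.T.col(enter) * (dir * step);
      S.at_upper[enter] = !S.at_upper[enter];
      continue;
    }

    // pivot: entering becomes basic at value rest + dir*step
    double enter_val = (S.at_upper[enter] ? S.ub[enter] : S.lb[enter]) + dir * step;
    S.xB -= S.T.col(enter) * (dir * step);
    int out = S.basis[leave_row];
    S.in_basis[out] = false;
    S.at_upper[out] = (leave_coef < 0);  // hit upper bound if coef negative
    S.basis[leave_row] = enter;
    S.in_basis[enter] = true;
    S.xB[leave_row] = enter_val;

    double piv = S.T(leave_row, enter);
    S.T.row(leave_row) /= piv;
    arma::vec col = S.T.col(enter);
    col[leave_row] = 0.0;
    S.T -= col * S.T.row(leave_row);
    // keep the entering column numerically clean
    S.T.col(enter).zeros();
    S.T(leave_row, enter) = 1.0;
  }
  return 2;
}

// [[Rcpp::export(name = ".lp_solve_cpp")]]
List lp_solve_cpp(const arma::vec &c, const arma::mat &A, const arma::vec &b,
                  const arma::vec &lb, const arma::vec &ub, int max_iter = 50000) {
  const int m = A.n_rows, n = A.n_cols;
  SimplexState S;
  S.m = m;
  S.ncol = n + m;
  S.lb = arma::join_cols(lb, arma::zeros(m));
  S.ub = arma::join_cols(ub, arma::vec(m));
  S.at_upper.assign(S.ncol, false);
  S.in_basis.assign(S.ncol, false);

  // start: structural variables at lower bound, artificials cover residual
  arma::vec r = b - A * lb;
  arma::vec s(m);
  for (int i = 0; i < m; ++i) s[i] = (r[i] >= 0) ? 1.0 : -1.0;
  S.T.set_size(m, S.ncol);
  S.T.cols(0, n - 1) = arma::diagmat(s) * A;
  S.T.cols(n, S.ncol - 1) = arma::eye(m, m);
  S.xB = arma::abs(r);
  S.basis.set_size(m);
  for (int i = 0; i < m; ++i) {
    S.basis[i] = n + i;
    S.in_basis[n + i] = true;
    S.ub[n + i] = std::abs(r[i]) + 1.0;
  }

  // phase 1
  arma::vec c1 = arma::join_cols(arma::zeros(n), arma::ones(m));
  int st = simplex_phase(S, c1, max_iter);
  if (st != 0) return List::create(_["status"] = 2);
  double art_sum = 0.0;
  for (int i = 0; i < m; ++i) if ((int)S.basis[i] >= n) art_sum += S.xB[i];
  if (art_sum > FEAS_TOL)
    return List::create(_["status"] = 1);  // infeasible

  // pin artificials to zero; pivot basic ones out where possible
  for (int j = n; j < S.ncol; ++j) S.ub[j] = 0.0;
  for (int i = 0; i < m; ++i) {
    if ((int)S.basis[i] < n) continue;
    int enter = -1;
    for (int j = 0; j < n; ++j) {
      if (S.in_basis[j]) continue;
      if (std::abs(S.T(i, j)) > 1e-7) { enter = j; break; }
    }
    if (enter < 0) continue;  // redundant row; artificial stays basic at 0
    int out = S.basis[i];
    S.in_basis[out] = false;
    S.at_upper[out] = false;
    S.basis[i] = enter;
    S.in_basis[enter] = true;
    double enter_val = S.at_upper[enter] ? S.ub[enter] : S.lb[enter];
    S.xB[i] = enter_val;  // degenerate pivot (artificial was 0)
    double piv = S.T(i, enter);
    S.T.row(i) /= piv;
    arma::vec col = S.T.col(enter);
    col[i] = 0.0;
    S.T -= col * S.T.row(i);
    S.T.col(enter).zeros();
    S.T(i, enter) = 1.0;
  }

  // phase 2
  arma::vec c2 = arma::join_cols(c, arma::zeros(m));
  st = simplex_phase(S, c2, max_iter);
  if (st != 0) return List::create(_["status"] = 2);

  arma::vec x(n);
  for (int j = 0; j < n; ++j)
    x[j] = S.in_basis[j] ? 0.0 : (S.at_upper[j] ? S.ub[j] : S.lb[j]);
  for (int i = 0; i < m; ++i)
    if ((int)S.basis[i] < n) x[S.basis[i]] = S.xB[i];
  return List::create(_["status"] = 0, _["x"] = x,
                      _["obj"] = arma::dot(c, x));
}
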