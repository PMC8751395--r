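// Dense bounded-variable primal simplex used by the flux-analysis routines.
//
// Solves  max/min  c'x   s.t.  A x = b,  lb <= x <= ub
// via a two-phase method with artificial variables. Problem sizes in this
// package are small (toy networks and split pFBA systems, tens to a few
// hundred columns), so a dense tableau with an explicitly maintained basis
// inverse is adequate; the inverse is refreshed periodically for stability.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct SimplexState {
  arma::mat A;             // m x N, structural columns then artificials
  arma::vec b, lb, ub, c;
  arma::uvec basis;        // m basic column indices
  std::vector<int> vstat;  // 0 = nonbasic at lb, 1 = nonbasic at ub, 2 = basic
  arma::vec x;             // length N
  arma::mat Binv;
};

static bool refactor(SimplexState &S) {
  arma::mat B = S.A.cols(S.basis);
  arma::mat Bi;
  if (!arma::inv(Bi, B)) return false;
  S.Binv = Bi;
  arma::vec rhs = S.b;
  for (arma::uword j = 0; j < S.A.n_cols; ++j)
    if (S.vstat[j] != 2 && S.x[j] != 0.0) rhs -= S.A.col(j) * S.x[j];
  arma::vec xB = S.Binv * rhs;
  for (arma::uword i = 0; i < S.basis.n_elem; ++i) S.x[S.basis[i]] = xB[i];
  return true;
}

// Maximizes S.c' x. Returns 0 optimal, 1 unbounded, 2 iteration limit,
// 3 numerical failure.
static int simplex_iterate(SimplexState &S, int max_iter, double tol) {
  const arma::uword m = S.A.n_rows, N = S.A.n_cols;
  if (!refactor(S)) return 3;
  int degen = 0, since_refactor = 0;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec cB(m);
    for (arma::uword i = 0; i < m; ++i) cB[i] = S.c[S.basis[i]];
    arma::rowvec y = cB.t() * S.Binv;
    arma::rowvec d = S.c.t() - y * S.A;

    // Entering variable: Dantzig rule, Bland's rule after a degenerate streak
    // to guarantee termination.
    bool bland = degen > 2 * static_cast<int>(m + N);
    int enter = -1;
    double best = tol;
    for (arma::uword j = 0; j < N; ++j) {
      if (S.vstat[j] == 2) continue;
      if (S.ub[j] - S.lb[j] < 1e-12) continue;  // fixed variable
      double viol = (S.vstat[j] == 0) ? d[j] : -d[j];
      if (viol > tol) {
        if (bland) { enter = static_cast<int>(j); break; }
        if (viol > best) { best = viol; enter = static_cast<int>(j); }
      }
    }
    if (enter < 0) return 0;

    double delta = (S.vstat[enter] == 0) ? 1.0 : -1.0;
    arma::vec w = S.Binv * S.A.col(enter);

    // Ratio test over basics plus the entering variable's opposite bound.
    double tmax = S.ub[enter] - S.lb[enter];
    int leave = -1, leave_to = 0;
    for (arma::uword i = 0; i < m; ++i) {
      double g = -delta * w[i];
      arma::uword k = S.basis[i];
      double t;
      int to;
      if (g > tol) {
        if (!std::isfinite(S.ub[k])) continue;
        t = (S.ub[k] - S.x[k]) / g; to = 1;
      } else if (g < -tol) {
        if (!std::isfinite(S.lb[k])) continue;
        t = (S.lb[k] - S.x[k]) / g; to = 0;
      } else {
        continue;
      }
      if (t < 0) t = 0;  // tiny bound violations from roundoff
      bool better = t < tmax - 1e-12;
      bool tie = bland && leave >= 0 && t <= tmax + 1e-12 &&
                 k < S.basis[static_cast<arma::uword>(leave)];
      if (better || tie) { tmax = t; leave = static_cast<int>(i); leave_to = to; }
    }
    if (!std::isfinite(tmax)) return 1;
    degen = (tmax < 1e-11) ? degen + 1 : 0;

    for (arma::uword i = 0; i < m; ++i) S.x[S.basis[i]] -= delta * w[i] * tmax;
    S.x[enter] += delta * tmax;

    if (leave < 0) {
      // Bound flip: entering variable crosses to its other bound.
      S.vstat[enter] = 1 - S.vstat[enter];
      S.x[enter] = (S.vstat[enter] == 0) ? S.lb[enter] : S.ub[enter];
    } else {
      arma::uword out = S.basis[static_cast<arma::uword>(leave)];
      double piv = w[static_cast<arma::uword>(leave)];
      if (std::abs(piv) < 1e-11) {
        if (!refactor(S)) return 3;
        continue;
      }
      S.vstat[out] = leave_to;
      S.x[out] = (leave_to == 0) ? S.lb[out] : S.ub[out];
      S.basis[static_cast<arma::uword>(leave)] = static_cast<arma::uword>(enter);
      S.vstat[enter] = 2;
      S.Binv.row(static_cast<arma::uword>(leave)) /= piv;
      for (arma::uword i = 0; i < m; ++i) {
        if (static_cast<int>(i) == leave) continue;
        double wi = w[i];
        if (wi != 0.0)
          S.Binv.row(i) -= wi * S.Binv.row(static_cast<arma::uword>(leave));
      }
    }
    if (++since_refactor >= 80) {
      since_refactor = 0;
      if (!refactor(S)) return 3;
    }
  }
  return 2;
}

//' @noRd
// [[Rcpp::export(name = ".simplex_lp")]]
List simplex_lp(arma::vec obj, arma::mat A, arma::vec b, arma::vec lb,
                arma::vec ub, bool maximize = true, int max_iter = 50000,
                double tol = 1e-9) {
  const arma::uword m = A.n_rows, n = A.n_cols;
  if (obj.n_elem != n || lb.n_elem != n || ub.n_elem != n || b.n_elem != m)
    stop("inconsistent LP dimensions");
  for (arma::uword j = 0; j < n; ++j) {
    if (!std::isfinite(lb[j]) || !std::isfinite(ub[j]))
      stop("simplex_lp requires finite variable bounds");
    if (lb[j] > ub[j] + 1e-9)
      return List::create(_["status"] = "infeasible",
                          _["x"] = NumericVector(n), _["objval"] = NA_REAL);
  }

  arma::vec c = maximize ? obj : arma::vec(-obj);

  if (n == 0) {
    bool ok = (m == 0) || arma::norm(b, "inf") < 1e-9;
    return List::create(_["status"] = ok ? "optimal" : "infeasible",
                        _["x"] = NumericVector(0),
                        _["objval"] = ok ? 0.0 : NA_REAL);
  }
  if (m == 0) {
    arma::vec x(n);
    for (arma::uword j = 0; j < n; ++j)
      x[j] = (c[j] > 0) ? ub[j] : ((c[j] < 0) ? lb[j]
              : (std::abs(lb[j]) <= std::abs(ub[j]) ? lb[j] : ub[j]));
    return List::create(_["status"] = "optimal", _["x"] = wrap(x),
                        _["objval"] = arma::dot(obj, x));
  }

  SimplexState S;
  S.A = arma::join_rows(A, arma::mat(m, m, arma::fill::zeros));
  S.b = b;
  S.lb = arma::join_cols(lb, arma::vec(m, arma::fill::zeros));
  S.ub = arma::join_cols(ub, arma::vec(m, arma::fill::value(INF)));
  S.x = arma::vec(n + m, arma::fill::zeros);
  S.vstat.assign(n + m, 0);
  S.basis = arma::uvec(m);

  // Structural variables start at the bound nearest zero.
  for (arma::uword j = 0; j < n; ++j) {
    bool at_lb = std::abs(lb[j]) <= std::abs(ub[j]);
    S.x[j] = at_lb ? lb[j] : ub[j];
    S.vstat[j] = at_lb ? 0 : 1;
  }
  arma::vec r = b - A * S.x.head(n);
  for (arma::uword i = 0; i < m; ++i) {
    double s = (r[i] >= 0) ? 1.0 : -1.0;
    S.A(i, n + i) = s;
    S.x[n + i] = std::abs(r[i]);
    S.vstat[n + i] = 2;
    S.basis[i] = n + i;
  }

  // Phase 1: drive artificials to zero.
  S.c = arma::join_cols(arma::vec(n, arma::fill::zeros),
                        arma::vec(m, arma::fill::value(-1.0)));
  int rc = simplex_iterate(S, max_iter, tol);
  if (rc == 3)
    return List::create(_["status"] = "numerical_failure",
                        _["x"] = NumericVector(n), _["objval"] = NA_REAL);
  double art = arma::accu(S.x.tail(m));
  if (rc == 2 || art > 1e-7)
    return List::create(_["status"] = (rc == 2) ? "iteration_limit"
                                                : "infeasible",
                        _["x"] = NumericVector(n), _["objval"] = NA_REAL);

  // Phase 2: fix artificials at zero and optimize the true objective.
  for (arma::uword i = 0; i < m; ++i) {
    S.ub[n + i] = 0.0;
    if (S.vstat[n + i] != 2) S.x[n + i] = 0.0;
  }
  S.c = arma::join_cols(c, arma::vec(m, arma::fill::zeros));
  rc = simplex_iterate(S, max_iter, tol);

  std::string status = "optimal";
  if (rc == 1) status = "unbounded";
  else if (rc == 2) status = "iteration_limit";
  else if (rc == 3) status = "numerical_failure";

  arma::vec x = S.x.head(n);
  double objval = arma::dot(obj, x);
  return List::create(_["status"] = status, _["x"] = wrap(x),
                      _["objval"] = (rc == 0) ? objval : NA_REAL);
}
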