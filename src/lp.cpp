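// Dense-tableau primal simplex for the L1-penalised double-hinge master
// problem, kept alive across column-generation rounds so each new rule
// column warm-starts from the previous optimal basis.
//
// Primal (min), with k = (1-d)/d >= 1 and per-sample cost C_i:
//   min  sum_j (a+_j + a-_j) + sum_i C_i xi_i
//   s.t. y_i (sum_j (a+_j - a-_j) h_j(x_i) + b+ - b-) + xi_i     >= 1
//        k y_i (sum_j (a+_j - a-_j) h_j(x_i) + b+ - b-) + xi_i   >= 1
//        a+, a-, b+, b-, xi >= 0
// Rows 2i / 2i+1 hold the unit-slope and k-slope constraint of sample i.
// The dual multipliers (alpha_{2i}, alpha_{2i+1}) give the mining weight
// u_i = alpha_{2i} + k * alpha_{2i+1}.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double DTOL = 1e-9;   // reduced-cost tolerance
const double PTOL = 1e-9;   // pivot-element tolerance

class MasterLP {
public:
  int n;                    // samples
  int nrow;                 // 2n constraint rows
  double k;                 // (1-d)/d
  std::vector<double> y;    // labels, +1/-1
  std::vector<double> C;    // per-sample misclassification cost C_{y_i}

  // column-major tableau: cols[c][r] = (B^{-1} A)[r][c]
  std::vector< std::vector<double> > cols;
  std::vector<double> cost;  // original objective coefficient per column
  std::vector<double> d;     // reduced costs
  std::vector<double> rhs;   // B^{-1} b
  std::vector<int> basis;    // row -> column index
  std::vector<int> in_basis; // column -> row index or -1
  double obj;
  long pivots;

  // column layout: [xi_0..xi_{n-1}] [b+ b-] [s_0..s_{2n-1}] [a+_0 a-_0 ...]
  int col_bplus, col_bminus, col_surplus0, col_rules0;
  int nrules;
  // rule activation vectors kept so the caller can audit columns
  std::vector< std::vector<int> > rule_cols;

  MasterLP(const NumericVector& y_, double k_, const NumericVector& C_)
      : n(y_.size()), nrow(2 * y_.size()), k(k_), obj(0.0), pivots(0),
        nrules(0) {
    y.assign(y_.begin(), y_.end());
    C.assign(C_.begin(), C_.end());
    col_bplus = n;
    col_bminus = n + 1;
    col_surplus0 = n + 2;
    col_rules0 = n + 2 + nrow;

    int ncol = col_rules0;
    cols.assign(ncol, std::vector<double>(nrow, 0.0));
    cost.assign(ncol, 0.0);
    d.assign(ncol, 0.0);
    rhs.assign(nrow, 0.0);
    basis.assign(nrow, -1);
    in_basis.assign(ncol, -1);

    // initial basis: xi_i basic on row 2i, surplus of row 2i+1 basic there;
    // B^{-1} has per-sample blocks [[1,0],[1,-1]], so for an original
    // column A: T[2i] = A[2i], T[2i+1] = A[2i] - A[2i+1].
    double sCy = 0.0;
    for (int i = 0; i < n; ++i) sCy += C[i] * y[i];

    for (int i = 0; i < n; ++i) {
      cols[i][2 * i] = 1.0;                   // xi_i
      cost[i] = C[i];
      d[i] = 0.0;
      basis[2 * i] = i;
      in_basis[i] = 2 * i;

      // b+ : A[2i] = y_i, A[2i+1] = k y_i
      cols[col_bplus][2 * i] = y[i];
      cols[col_bplus][2 * i + 1] = y[i] * (1.0 - k);
      cols[col_bminus][2 * i] = -y[i];
      cols[col_bminus][2 * i + 1] = -y[i] * (1.0 - k);

      // surplus columns (original A = -e_r)
      int s0 = col_surplus0 + 2 * i, s1 = col_surplus0 + 2 * i + 1;
      cols[s0][2 * i] = -1.0;
      cols[s0][2 * i + 1] = -1.0;
      cols[s1][2 * i + 1] = 1.0;
      d[s0] = C[i];
      d[s1] = 0.0;
      basis[2 * i + 1] = s1;
      in_basis[s1] = 2 * i + 1;

      rhs[2 * i] = 1.0;
      rhs[2 * i + 1] = 0.0;
      obj += C[i];
    }
    d[col_bplus] = -sCy;
    d[col_bminus] = sCy;
  }

  int ncol() const { return (int)cols.size(); }

  // dual multiplier of constraint row r (= reduced cost of its surplus col)
  double dual(int r) const {
    double v = d[col_surplus0 + r];
    return v < 0.0 ? 0.0 : v;
  }

  // append the a+/a- pair for a rule with 0/1 activation h over samples
  int add_rule_column(const IntegerVector& h) {
    if ((int)h.size() != n) stop("activation vector length must equal n");
    std::vector<double> tp(nrow, 0.0);
    double ydA = 0.0;  // sum_r dual_r * A[r]
    for (int i = 0; i < n; ++i) {
      if (h[i] == 0) continue;
      double a0 = y[i], a1 = k * y[i];
      // B^{-1} column r is -cols[surplus_r]
      const std::vector<double>& s0 = cols[col_surplus0 + 2 * i];
      const std::vector<double>& s1 = cols[col_surplus0 + 2 * i + 1];
      for (int r = 0; r < nrow; ++r) tp[r] -= a0 * s0[r] + a1 * s1[r];
      ydA += d[col_surplus0 + 2 * i] * a0 + d[col_surplus0 + 2 * i + 1] * a1;
    }
    std::vector<double> tm(nrow);
    for (int r = 0; r < nrow; ++r) tm[r] = -tp[r];
    cols.push_back(tp);
    cost.push_back(1.0);
    d.push_back(1.0 - ydA);
    in_basis.push_back(-1);
    cols.push_back(tm);
    cost.push_back(1.0);
    d.push_back(1.0 + ydA);
    in_basis.push_back(-1);
    rule_cols.push_back(std::vector<int>(h.begin(), h.end()));
    return nrules++;
  }

  void pivot(int r, int q) {
    std::vector<double> e(cols[q]);  // entering column values
    double piv = e[r];
    double dq = d[q];
    int nc = ncol();
    for (int c = 0; c < nc; ++c) {
      if (c == q) continue;
      std::vector<double>& tc = cols[c];
      double cr = tc[r] / piv;
      if (cr != 0.0) {
        for (int i = 0; i < nrow; ++i) tc[i] -= e[i] * cr;
        tc[r] = cr;
      }
      d[c] -= dq * cr;
    }
    double rr = rhs[r] / piv;
    for (int i = 0; i < nrow; ++i) rhs[i] -= e[i] * rr;
    rhs[r] = rr;
    obj += dq * rr;
    for (int i = 0; i < nrow; ++i)
      if (rhs[i] < 0.0) rhs[i] = (rhs[i] > -1e-7) ? 0.0 : rhs[i];

    int leaving = basis[r];
    in_basis[leaving] = -1;
    basis[r] = q;
    in_basis[q] = r;
    std::fill(cols[q].begin(), cols[q].end(), 0.0);
    cols[q][r] = 1.0;
    d[q] = 0.0;
    ++pivots;
  }

  // primal simplex to optimality; Dantzig rule with a Bland fallback
  // after a run of degenerate pivots (anti-cycling)
  void solve() {
    long maxpiv = 200L * nrow + 20000L;
    int degen = 0;
    bool bland = false;
    long local = 0;
    while (true) {
      if (++local > maxpiv)
        stop("simplex iteration limit exceeded (%ld pivots)", maxpiv);
      int q = -1;
      if (!bland) {
        double best = -DTOL;
        for (int c = 0; c < ncol(); ++c)
          if (d[c] < best) { best = d[c]; q = c; }
      } else {
        for (int c = 0; c < ncol(); ++c)
          if (d[c] < -DTOL) { q = c; break; }
      }
      if (q < 0) break;  // optimal

      const std::vector<double>& tq = cols[q];
      int r = -1;
      double theta = std::numeric_limits<double>::infinity();
      double bestpiv = 0.0;
      for (int i = 0; i < nrow; ++i) {
        if (tq[i] > PTOL) {
          double ratio = rhs[i] / tq[i];
          if (ratio < theta - 1e-12) {
            theta = ratio; r = i; bestpiv = tq[i];
          } else if (ratio < theta + 1e-12 && r >= 0) {
            if (bland) {
              if (basis[i] < basis[r]) { r = i; bestpiv = tq[i]; }
            } else if (tq[i] > bestpiv) {
              r = i; bestpiv = tq[i];
            }
          }
        }
      }
      if (r < 0)
        stop("LP unbounded: no blocking row for entering column %d", q);
      double before = obj;
      pivot(r, q);
      if (obj > before - 1e-12) {
        if (++degen > 200) bland = true;
      } else {
        degen = 0; bland = false;
      }
    }
  }

  double value(int c) const {
    int r = in_basis[c];
    return r >= 0 ? rhs[r] : 0.0;
  }

  List solution() const {
    NumericVector w(nrules), xi(n), u(n), alpha(nrow);
    for (int j = 0; j < nrules; ++j)
      w[j] = value(col_rules0 + 2 * j) - value(col_rules0 + 2 * j + 1);
    for (int i = 0; i < n; ++i) xi[i] = value(i);
    for (int r = 0; r < nrow; ++r) alpha[r] = dual(r);
    for (int i = 0; i < n; ++i) u[i] = alpha[2 * i] + k * alpha[2 * i + 1];
    double b = value(col_bplus) - value(col_bminus);
    return List::create(
        _["weights"] = w, _["bias"] = b, _["xi"] = xi,
        _["objective"] = obj, _["alpha"] = alpha, _["u"] = u,
        _["pivots"] = (double)pivots);
  }
};

}  // namespace

// [[Rcpp::export(name = ".lp_create")]]
SEXP lp_create(NumericVector y, double k, NumericVector C) {
  if (C.size() != y.size()) stop("y and C must have equal length");
  MasterLP* p = new MasterLP(y, k, C);
  XPtr<MasterLP> ptr(p, true);
  return ptr;
}

// [[Rcpp::export(name = ".lp_add_column")]]
int lp_add_column(SEXP lp, IntegerVector h) {
  XPtr<MasterLP> ptr(lp);
  return ptr->add_rule_column(h);
}

// [[Rcpp::export(name = ".lp_solve")]]
List lp_solve(SEXP lp) {
  XPtr<MasterLP> ptr(lp);
  ptr->solve();
  return ptr->solution();
}
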