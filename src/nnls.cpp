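// Lawson-Hanson active-set non-negative least squares, plus the
// simplex-constrained row solver built on it.  The simplex constraint
// (w >= 0, sum w = 1) is enforced by augmenting the system with a heavily
// weighted sum-to-one equation; the augmentation weight is supplied by the
// caller so it can be scaled to the data.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||C x - d||^2 subject to x >= 0.
// Standard Lawson-Hanson: grow a passive set by the most positive gradient
// component, solve the unconstrained LS on the passive set, step back to the
// feasible boundary when the candidate goes negative.
static vec nnls_one(const mat& C, const vec& d, const double tol,
                    const int max_outer) {
  const uword p = C.n_cols;
  vec x(p, fill::zeros);
  std::vector<uword> passive;
  uvec in_passive(p, fill::zeros);
  vec w = C.t() * (d - C * x);  // negative gradient

  int outer = 0;
  while (outer++ < max_outer) {
    // pick the best violated coordinate not yet passive
    double wmax = tol;
    sword jmax = -1;
    for (uword j = 0; j < p; ++j) {
      if (!in_passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0) break;  // KKT satisfied
    passive.push_back((uword)jmax);
    in_passive((uword)jmax) = 1;

    // inner loop: LS on passive set, retreating while infeasible
    for (;;) {
      uvec P = conv_to<uvec>::from(passive);
      mat CP = C.cols(P);
      vec z;
      bool ok = solve(z, CP, d, solve_opts::fast + solve_opts::no_approx);
      if (!ok) z = pinv(CP) * d;
      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step from x(P) toward z until the first coordinate hits zero
      double alpha = 1.0;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (z(i) <= 0) {
          double xi = x(P(i));
          double a = xi / (xi - z(i));
          if (a < alpha) alpha = a;
        }
      }
      for (uword i = 0; i < P.n_elem; ++i)
        x(P(i)) += alpha * (z(i) - x(P(i)));
      // drop coordinates that reached zero
      std::vector<uword> keep;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (x(P(i)) > tol) keep.push_back(P(i));
        else { x(P(i)) = 0.0; in_passive(P(i)) = 0; }
      }
      passive = keep;
      if (passive.empty()) break;
    }
    w = C.t() * (d - C * x);
  }
  return x;
}

// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::NumericVector nnls_cpp(const arma::mat& C, const arma::vec& d) {
  vec x = nnls_one(C, d, 10.0 * datum::eps * norm(C, "inf") * C.n_cols, 30 * C.n_cols);
  return Rcpp::NumericVector(x.begin(), x.end());
}

// Solve, for every row t of `targets`, min ||t - w B||^2 over the probability
// simplex, via NNLS on the augmented system [B', M1]' w ~ [t, M]'.
// Returns an n x k matrix of weights, renormalized to sum exactly to one.
// [[Rcpp::export(name = ".simplex_ls_rows_cpp")]]
Rcpp::NumericMatrix simplex_ls_rows_cpp(const arma::mat& targets,
                                        const arma::mat& basis,
                                        const double M) {
  const uword n = targets.n_rows, m = targets.n_cols, k = basis.n_rows;
  if (basis.n_cols != m) Rcpp::stop("dimension mismatch between targets and basis");
  mat C(m + 1, k);
  C.rows(0, m - 1) = basis.t();
  C.row(m).fill(M);
  const double tol = 10.0 * datum::eps * norm(C, "inf") * k;
  mat W(n, k);
  vec d(m + 1);
  for (uword i = 0; i < n; ++i) {
    d.subvec(0, m - 1) = targets.row(i).t();
    d(m) = M;
    vec w = nnls_one(C, d, tol, 30 * k);
    double s = accu(w);
    if (s <= 0) { w.fill(1.0 / k); s = 1.0; }  // degenerate target
    W.row(i) = (w / s).t();
  }
  return Rcpp::wrap(W);
}
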