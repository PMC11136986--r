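// Per-voxel simplex-constrained least squares.
//
// For each column y of Y solve
//   min_w || y - A w ||^2   s.t.  w >= 0,  sum(w) = 1
// by a primal active-set method (Lawson-Hanson structure with the equality
// constraint carried in the KKT system). M = ncol(A) is small (the number of
// spectral components), so each KKT solve is a tiny dense system; the batch
// loop over voxels lives here rather than in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve the equality-constrained subproblem on the free set P:
//   min 1/2 z' Q_PP z - c_P' z   s.t.  1'z = 1
// via the KKT system. Returns false if the system is singular even after a
// small ridge.
static bool solve_kkt(const mat& Q, const vec& c, const uvec& P,
                      vec& z, double& nu) {
  const uword k = P.n_elem;
  mat KKT(k + 1, k + 1, fill::zeros);
  KKT.submat(0, 0, k - 1, k - 1) = Q.submat(P, P);
  KKT.submat(0, k, k - 1, k).fill(1.0);
  KKT.submat(k, 0, k, k - 1).fill(1.0);
  vec rhs(k + 1);
  rhs.subvec(0, k - 1) = c.elem(P);
  rhs(k) = 1.0;
  vec sol;
  bool ok = solve(sol, KKT, rhs, solve_opts::no_approx);
  if (!ok) {
    mat KKT2 = KKT;
    double ridge = 1e-10 * (1.0 + trace(Q) / Q.n_rows);
    KKT2.submat(0, 0, k - 1, k - 1).diag() += ridge;
    ok = solve(sol, KKT2, rhs, solve_opts::no_approx);
    if (!ok) return false;
  }
  z = sol.subvec(0, k - 1);
  nu = sol(k);
  return true;
}

// Single-voxel solve given Q = A'A and c = A'y.
static vec simplex_lsq_one(const mat& Q, const vec& c, double tol) {
  const uword M = Q.n_rows;
  if (M == 1) return vec(1, fill::ones);

  // start from the best single-component vertex: max 2*c_j - Q_jj
  vec score = 2.0 * c - Q.diag();
  uword j0 = score.index_max();
  vec w(M, fill::zeros);
  w(j0) = 1.0;
  std::vector<uword> free_set{j0};

  const uword max_iter = 50 * (M + 1);
  for (uword iter = 0; iter < max_iter; ++iter) {
    uvec P(free_set);
    vec z;
    double nu;
    if (!solve_kkt(Q, c, P, z, nu)) break;

    if (z.min() > -tol) {
      // feasible on the free set; check optimality over the bound set
      w.zeros();
      for (uword i = 0; i < P.n_elem; ++i) w(P(i)) = std::max(z(i), 0.0);
      vec mu = Q * w - c + nu;  // multipliers for w_j >= 0 (zero on P)
      double worst = 0.0;
      sword add = -1;
      for (uword j = 0; j < M; ++j) {
        bool in_free = false;
        for (uword i = 0; i < P.n_elem; ++i)
          if (P(i) == j) { in_free = true; break; }
        if (!in_free && mu(j) < worst) { worst = mu(j); add = (sword)j; }
      }
      if (add < 0 || worst > -tol) break;  // KKT satisfied
      free_set.push_back((uword)add);
    } else {
      // step towards z until the first free weight hits zero; drop it
      double alpha = 1.0;
      sword drop = -1;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (z(i) < tol) {
          double denom = w(P(i)) - z(i);
          if (denom > 0) {
            double a = w(P(i)) / denom;
            if (a < alpha) { alpha = a; drop = (sword)i; }
          }
        }
      }
      for (uword i = 0; i < P.n_elem; ++i)
        w(P(i)) = std::max(w(P(i)) + alpha * (z(i) - w(P(i))), 0.0);
      if (drop >= 0) {
        w(P((uword)drop)) = 0.0;
        free_set.erase(free_set.begin() + drop);
      }
      if (free_set.empty()) {  // numerical corner; restart from best vertex
        w.zeros();
        w(j0) = 1.0;
        free_set.push_back(j0);
      }
    }
  }
  // exact renormalisation guards accumulated round-off
  double s = accu(w);
  if (s > 0) w /= s; else w.fill(1.0 / M);
  return w;
}

//' @title Batch simplex-constrained least squares (internal)
//' @description For each column of \code{Y}, minimises the squared residual
//'   against the dictionary \code{A} subject to non-negative weights summing
//'   to one. Used for per-voxel component unmixing.
//' @param A numeric matrix (measurements x components).
//' @param Y numeric matrix (measurements x voxels).
//' @return matrix of weights (components x voxels).
//' @keywords internal
// [[Rcpp::export(name = ".simplex_lsq_batch")]]
arma::mat simplex_lsq_batch(const arma::mat& A, const arma::mat& Y) {
  if (A.n_rows != Y.n_rows)
    Rcpp::stop("A and Y must have the same number of rows");
  mat Q = A.t() * A;
  double tol = 1e-12 * (1.0 + Q.diag().max());
  mat C = A.t() * Y;  // columns are c vectors
  mat W(A.n_cols, Y.n_cols);
  for (uword v = 0; v < Y.n_cols; ++v) {
    W.col(v) = simplex_lsq_one(Q, C.col(v), tol);
  }
  return W;
}
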