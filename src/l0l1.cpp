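// Coordinate-descent + local-swap solver for the L0+L1 penalized
// least-squares objective
//   J(beta) = (1/2)||y - X beta||^2 + lambda0*||beta||_0 + lambda1*||beta||_1
// All routines assume y is centered; columns of X are expected to have unit
// sum of squares (the R wrappers standardize), but the updates use the true
// diagonal of the Gram matrix so other scalings remain correct.
//
// Updates are "covariance" style: with G = X'X, q = X'y and the running
// correlation vector r = q - G beta, a coordinate update and a swap
// evaluation are both O(p), independent of n.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// Exact scalar minimizer of the 1-D subproblem in coordinate j:
// t = soft(rho, lambda1)/d kept only if the improvement (1/2) d t^2 over
// beta_j = 0 covers the per-nonzero cost lambda0.
static inline double threshold_update_cpp(double rho, double d,
                                          double lambda0, double lambda1) {
  if (d <= 0.0) return 0.0;
  double t = soft(rho, lambda1) / d;
  if (0.5 * d * t * t >= lambda0 && t != 0.0) return t;
  return 0.0;
}

struct WorkState {
  const arma::mat& G;
  const arma::vec& q;
  arma::vec diag;
  double yty;
  arma::vec beta;
  arma::vec r; // q - G beta

  WorkState(const arma::mat& G_, const arma::vec& q_, double yty_,
            const arma::vec& beta0)
      : G(G_), q(q_), diag(G_.diag()), yty(yty_), beta(beta0) {
    r = q - G * beta;
  }

  double objective(double lambda0, double lambda1) const {
    double quad = 0.5 * yty - 0.5 * arma::dot(beta, q + r);
    double l0 = 0.0, l1 = 0.0;
    for (arma::uword j = 0; j < beta.n_elem; ++j) {
      if (beta[j] != 0.0) {
        l0 += 1.0;
        l1 += std::fabs(beta[j]);
      }
    }
    return quad + lambda0 * l0 + lambda1 * l1;
  }

  void set_coord(arma::uword j, double newb) {
    double delta = newb - beta[j];
    if (delta != 0.0) {
      r -= G.col(j) * delta;
      beta[j] = newb;
    }
  }
};

// One full cyclic sweep; returns true if any coefficient moved.
static bool cd_sweep(WorkState& st, double lambda0, double lambda1) {
  bool moved = false;
  arma::uword p = st.beta.n_elem;
  for (arma::uword j = 0; j < p; ++j) {
    double rho = st.r[j] + st.diag[j] * st.beta[j];
    double nb = threshold_update_cpp(rho, st.diag[j], lambda0, lambda1);
    if (nb != st.beta[j]) {
      st.set_coord(j, nb);
      moved = true;
    }
  }
  return moved;
}

// Run CD sweeps to (relative-objective) convergence; the objective after
// every sweep is appended to trace.
static int cd_until_converged(WorkState& st, double lambda0, double lambda1,
                              double tol, int max_iter, bool& converged,
                              std::vector<double>& trace) {
  double obj = st.objective(lambda0, lambda1);
  int it = 0;
  converged = false;
  while (it < max_iter) {
    bool moved = cd_sweep(st, lambda0, lambda1);
    ++it;
    double newobj = st.objective(lambda0, lambda1);
    trace.push_back(newobj);
    double denom = std::max(std::fabs(obj), 1.0);
    if (!moved || std::fabs(obj - newobj) / denom < tol) {
      converged = true;
      obj = newobj;
      break;
    }
    obj = newobj;
  }
  return it;
}

// Best single swap (drop active j, admit inactive k at its optimal scalar
// coefficient). Returns true and fills (j*, k*, t*) if some swap strictly
// lowers the objective.
static bool best_swap(const WorkState& st, double lambda1, arma::uword& jbest,
                      arma::uword& kbest, double& tbest, double& delta_best) {
  arma::uword p = st.beta.n_elem;
  delta_best = -1e-10; // require strict improvement beyond noise
  bool found = false;
  for (arma::uword j = 0; j < p; ++j) {
    double b = st.beta[j];
    if (b == 0.0) continue;
    double removal = b * st.r[j] + 0.5 * st.diag[j] * b * b -
                     lambda1 * std::fabs(b);
    // correlations after removing j: r'_k = r_k + b * G_kj
    for (arma::uword k = 0; k < p; ++k) {
      if (k == j || st.beta[k] != 0.0 || st.diag[k] <= 0.0) continue;
      double rk = st.r[k] + b * st.G(k, j);
      double t = soft(rk, lambda1) / st.diag[k];
      if (t == 0.0) continue;
      double delta = removal - 0.5 * st.diag[k] * t * t;
      if (delta < delta_best) {
        delta_best = delta;
        jbest = j;
        kbest = k;
        tbest = t;
        found = true;
      }
    }
  }
  return found;
}

static List fit_one(WorkState& st, double lambda0, double lambda1, double tol,
                    int max_iter, int max_swaps) {
  bool converged = false;
  std::vector<double> trace;
  int iters = cd_until_converged(st, lambda0, lambda1, tol, max_iter,
                                 converged, trace);
  int swaps = 0;
  while (swaps < max_swaps) {
    arma::uword j, k;
    double t, delta;
    if (!best_swap(st, lambda1, j, k, t, delta)) break;
    st.set_coord(j, 0.0);
    st.set_coord(k, t);
    trace.push_back(st.objective(lambda0, lambda1));
    ++swaps;
    bool conv2 = false;
    iters += cd_until_converged(st, lambda0, lambda1, tol, max_iter, conv2,
                                trace);
    converged = converged && conv2;
  }
  return List::create(_["beta"] = st.beta,
                      _["objective"] = st.objective(lambda0, lambda1),
                      _["n_iterations"] = iters, _["n_swaps"] = swaps,
                      _["converged"] = converged,
                      _["trace"] = wrap(trace));
}

// [[Rcpp::export(name = ".cpp_fit_l0l1")]]
List cpp_fit_l0l1(const arma::mat& X, const arma::vec& y, double lambda0,
                  double lambda1, const arma::vec& beta_init, double tol,
                  int max_iter, int max_swaps) {
  arma::mat G = X.t() * X;
  arma::vec q = X.t() * y;
  double yty = arma::dot(y, y);
  WorkState st(G, q, yty, beta_init);
  return fit_one(st, lambda0, lambda1, tol, max_iter, max_swaps);
}

// Warm-started fits over the full lambda1 x lambda0 grid (both descending).
// Within each lambda1 the lambda0 path starts from zero and warm-starts
// downward. Returns a p x (n0*n1) coefficient matrix, column order:
// lambda1 outer, lambda0 inner.
// [[Rcpp::export(name = ".cpp_fit_path")]]
List cpp_fit_path(const arma::mat& X, const arma::vec& y,
                  const arma::vec& lambda0_grid, const arma::vec& lambda1_grid,
                  double tol, int max_iter, int max_swaps) {
  arma::uword p = X.n_cols;
  arma::uword n0 = lambda0_grid.n_elem, n1 = lambda1_grid.n_elem;
  arma::mat G = X.t() * X;
  arma::vec q = X.t() * y;
  double yty = arma::dot(y, y);

  arma::mat betas(p, n0 * n1, arma::fill::zeros);
  arma::vec objs(n0 * n1);
  IntegerVector iters(n0 * n1);
  LogicalVector conv(n0 * n1);

  for (arma::uword i1 = 0; i1 < n1; ++i1) {
    WorkState st(G, q, yty, arma::vec(p, arma::fill::zeros));
    for (arma::uword i0 = 0; i0 < n0; ++i0) {
      List res = fit_one(st, lambda0_grid[i0], lambda1_grid[i1], tol, max_iter,
                         max_swaps);
      arma::uword idx = i1 * n0 + i0;
      betas.col(idx) = st.beta;
      objs[idx] = as<double>(res["objective"]);
      iters[idx] = as<int>(res["n_iterations"]);
      conv[idx] = as<bool>(res["converged"]);
    }
  }
  return List::create(_["beta"] = betas, _["objective"] = objs,
                      _["n_iterations"] = iters, _["converged"] = conv);
}

// Brute-force reference: enumerate every support, solve the support-
// restricted L1 problem by plain cyclic soft-threshold CD (convex, no swaps,
// no warm starts), add lambda0 * (realized nonzeros), keep the best. Only
// feasible for small p; used as an independent optimum check.
// [[Rcpp::export(name = ".cpp_exhaustive_l0l1")]]
List cpp_exhaustive_l0l1(const arma::mat& X, const arma::vec& y,
                         double lambda0, double lambda1) {
  arma::uword p = X.n_cols;
  if (p > 20) stop("exhaustive search supports at most 20 columns");
  arma::mat G = X.t() * X;
  arma::vec q = X.t() * y;
  double yty = arma::dot(y, y);
  arma::vec diag = G.diag();

  double best_obj = 0.5 * yty; // empty support
  arma::vec best_beta(p, arma::fill::zeros);

  unsigned long nmask = 1UL << p;
  for (unsigned long mask = 1; mask < nmask; ++mask) {
    std::vector<arma::uword> S;
    for (arma::uword j = 0; j < p; ++j)
      if (mask & (1UL << j)) S.push_back(j);

    arma::vec beta(p, arma::fill::zeros);
    arma::vec r = q; // q - G beta with beta = 0
    double obj_prev = 0.5 * yty;
    for (int sweep = 0; sweep < 10000; ++sweep) {
      for (arma::uword idx = 0; idx < S.size(); ++idx) {
        arma::uword j = S[idx];
        if (diag[j] <= 0.0) continue;
        double rho = r[j] + diag[j] * beta[j];
        double nb = soft(rho, lambda1) / diag[j];
        if (nb != beta[j]) {
          r -= G.col(j) * (nb - beta[j]);
          beta[j] = nb;
        }
      }
      double quad = 0.5 * yty - 0.5 * arma::dot(beta, q + r);
      double obj = quad + lambda1 * arma::accu(arma::abs(beta));
      if (std::fabs(obj_prev - obj) / std::max(std::fabs(obj_prev), 1.0) < 1e-12)
        break;
      obj_prev = obj;
    }
    double quad = 0.5 * yty - 0.5 * arma::dot(beta, q + r);
    double l1 = arma::accu(arma::abs(beta));
    double nnz = 0;
    for (arma::uword j = 0; j < p; ++j)
      if (beta[j] != 0.0) nnz += 1.0;
    double obj = quad + lambda0 * nnz + lambda1 * l1;
    if (obj < best_obj) {
      best_obj = obj;
      best_beta = beta;
    }
  }
  return List::create(_["beta"] = best_beta, _["objective"] = best_obj);
}
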