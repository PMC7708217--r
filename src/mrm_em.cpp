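// EM for a finite mixture of RBF regressions with an l1 penalty on the
// per-cluster coefficient vectors, penalty weight lambda * pi_k (the mixing
// proportion), shared Gaussian noise variance across clusters.
//
// Units are profiles (subjects within a region, or regions within a subject);
// each unit contributes a block of rows of the stacked design matrix H.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Coordinate descent for min_w 0.5 w'Aw - b'w + pen * ||w||_1.
// A must be positive semi-definite with strictly positive diagonal (a ridge
// term is folded in by the caller). Warm-started from the incoming w.
static void cd_lasso(const mat& A, const vec& b, vec& w, double pen,
                     int max_sweep, double tol) {
  const uword J = A.n_cols;
  for (int s = 0; s < max_sweep; ++s) {
    double maxdelta = 0.0;
    for (uword j = 0; j < J; ++j) {
      const double ajj = A(j, j);
      if (ajj <= 0.0) { w(j) = 0.0; continue; }
      // partial residual correlation with w_j removed
      const double r = b(j) - dot(A.col(j), w) + ajj * w(j);
      const double wj = soft_threshold(r, pen) / ajj;
      const double d = std::abs(wj - w(j));
      if (d > maxdelta) maxdelta = d;
      w(j) = wj;
    }
    if (maxdelta < tol) break;
  }
}

// [[Rcpp::export]]
arma::vec cpp_cd_lasso(const arma::mat& A, const arma::vec& b, arma::vec w0,
                       double pen, int max_sweep = 2000, double tol = 1e-12) {
  cd_lasso(A, b, w0, pen, max_sweep, tol);
  return w0;
}

// Exact minimizer of 0.5 w'Aw - b'w + pen*||w||_1 by an active-set method
// in the style of Lawson-Hanson NNLS: solve the sign-restricted subproblem
// on the current active set; on a sign flip, step to the first zero
// crossing and deactivate that coordinate; at a sign-feasible solution,
// activate the single worst KKT violator. Warm-started from the incoming w;
// falls back to plain coordinate descent if the loop fails to terminate.
static void lasso_solve(const mat& A, const vec& b, vec& w, double pen,
                        int max_outer, int cd_sweeps, double cd_tol) {
  if (pen <= 0.0) {
    if (!solve(w, A, b, solve_opts::likely_sympd)) w = pinv(A) * b;
    return;
  }
  const uword J = A.n_cols;
  const double kkt_tol = pen * 1e-9 + 1e-12;
  cd_lasso(A, b, w, pen, 2, cd_tol); // cheap start to seed the sign pattern
  for (int outer = 0; outer < max_outer; ++outer) {
    const uvec act = find(abs(w) > 0);
    if (act.n_elem == 0) {
      const vec g = abs(b);
      const uword jmax = g.index_max();
      if (g(jmax) <= pen + kkt_tol) return; // w = 0 is optimal
      w(jmax) = soft_threshold(b(jmax), pen) / std::max(A(jmax, jmax), 1e-12);
      continue;
    }
    const vec s = sign(w.elem(act));
    vec wa;
    if (!solve(wa, A.submat(act, act), b.elem(act) - pen * s,
               solve_opts::likely_sympd)) {
      cd_lasso(A, b, w, pen, cd_sweeps, cd_tol);
      return;
    }
    if (any(wa % s < 0)) {
      // step toward wa until the first coefficient crosses zero
      const vec wact = w.elem(act);
      double alpha = 1.0;
      uword j_cross = 0;
      for (uword a = 0; a < act.n_elem; ++a) {
        if (wa(a) * s(a) < 0) {
          const double aj = wact(a) / (wact(a) - wa(a));
          if (aj < alpha) { alpha = aj; j_cross = a; }
        }
      }
      vec wnew = wact + alpha * (wa - wact);
      wnew(j_cross) = 0.0;
      w.zeros();
      w.elem(act) = wnew;
      continue;
    }
    vec wtry(J, fill::zeros);
    wtry.elem(act) = wa;
    const vec g = b - A * wtry;
    double worst = 0.0;
    uword j_worst = 0;
    for (uword j = 0; j < J; ++j) {
      if (wtry(j) != 0.0) continue;
      const double v = std::abs(g(j)) - pen;
      if (v > worst) { worst = v; j_worst = j; }
    }
    w = wtry;
    if (worst <= kkt_tol) return; // KKT satisfied: global optimum
    w(j_worst) = soft_threshold(g(j_worst), pen) /
                 std::max(A(j_worst, j_worst), 1e-12);
  }
  cd_lasso(A, b, w, pen, cd_sweeps, cd_tol); // safety net on non-termination
}

// [[Rcpp::export]]
arma::vec cpp_lasso_solve(const arma::mat& A, const arma::vec& b,
                          arma::vec w0, double pen, int max_outer = 25,
                          int cd_sweeps = 30, double cd_tol = 1e-11) {
  lasso_solve(A, b, w0, pen, max_outer, cd_sweeps, cd_tol);
  return w0;
}

// [[Rcpp::export]]
Rcpp::List cpp_em_fit(const arma::mat& H, const arma::vec& y,
                      const arma::ivec& unit, int n_units, arma::mat z,
                      double lambda, double ridge, int max_iter, double tol,
                      int cd_max_sweep = 30, double cd_tol = 1e-10,
                      double min_resp = 1e-6) {
  const uword J = H.n_cols;
  const uword P = H.n_rows;
  const int N = n_units;
  uword K = z.n_cols;

  // per-unit sufficient statistics
  cube G(J, J, N);
  mat Cmat(J, N);
  vec yy(N, fill::zeros), In(N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    uvec idx = find(unit == n);
    const mat Hn = H.rows(idx);
    const vec yn = y.elem(idx);
    G.slice(n) = Hn.t() * Hn;
    Cmat.col(n) = Hn.t() * yn;
    yy(n) = dot(yn, yn);
    In(n) = static_cast<double>(idx.n_elem);
  }
  const mat Gflat(G.memptr(), J * J, N); // copy view of the cube

  mat W(J, K, fill::zeros);
  vec pi(K);
  double sigma2 = var(y);
  if (!(sigma2 > 1e-10)) sigma2 = 1e-10;

  double pen_ll = -datum::inf, loglik = -datum::inf;
  std::vector<double> trace;
  bool converged = false;
  int n_dropped = 0, iter = 0;
  const double log2pi = std::log(2.0 * datum::pi);

  mat SSE(N, K);
  for (iter = 0; iter < max_iter; ++iter) {
    // ---- M-step (given responsibilities z) ----
    // Mixing proportions maximize the penalized bound
    //   sum_k S_k log pi_k - lambda * pi_k * ||w_k||_1  on the simplex:
    //   pi_k = S_k / (mu + lambda*||w_k||_1) with mu solving sum pi = 1
    // (reduces to pi_k = S_k / N when lambda = 0).
    {
      const vec S = sum(z, 0).t();
      vec c(K);
      for (uword k = 0; k < K; ++k) c(k) = lambda * norm(W.col(k), 1);
      if (lambda <= 0.0 || c.max() <= 0.0) {
        pi = S / static_cast<double>(N);
      } else {
        double lo = -c.min() + 1e-12, hi = static_cast<double>(N) + c.max();
        for (int it2 = 0; it2 < 200; ++it2) {
          const double mid = 0.5 * (lo + hi);
          double g = 0.0;
          for (uword k = 0; k < K; ++k) g += S(k) / (mid + c(k));
          if (g > 1.0) lo = mid; else hi = mid;
        }
        const double mu = 0.5 * (lo + hi);
        for (uword k = 0; k < K; ++k) pi(k) = S(k) / (mu + c(k));
        pi /= accu(pi); // wash out the residual bisection error
      }
    }
    for (uword k = 0; k < K; ++k) {
      mat A = reshape(Gflat * z.col(k), J, J);
      A.diag() += ridge;
      const vec b = Cmat * z.col(k);
      vec wk = W.col(k);
      lasso_solve(A, b, wk, lambda * pi(k) * sigma2, 60, cd_max_sweep,
                  cd_tol);
      W.col(k) = wk;
    }
    // residual sums of squares per unit x cluster under the new W
    for (int n = 0; n < N; ++n) {
      const mat GW = G.slice(n) * W; // J x K
      for (uword k = 0; k < K; ++k) {
        double s = yy(n) - 2.0 * dot(W.col(k), Cmat.col(n)) +
                   dot(W.col(k), GW.col(k));
        SSE(n, k) = (s > 0.0) ? s : 0.0;
      }
    }
    sigma2 = accu(z % SSE) / static_cast<double>(P);
    if (!(sigma2 > 1e-10)) sigma2 = 1e-10;

    // ---- E-step ----
    mat lp(N, K);
    for (uword k = 0; k < K; ++k)
      lp.col(k) = std::log(pi(k)) - 0.5 * In * (log2pi + std::log(sigma2)) -
                  SSE.col(k) / (2.0 * sigma2);
    const vec m = max(lp, 1);
    const vec lse = m + log(sum(exp(lp.each_col() - m), 1));
    loglik = accu(lse);
    if (!std::isfinite(loglik))
      Rcpp::stop("non-finite log-likelihood at EM iteration %d", iter + 1);
    z = exp(lp.each_col() - lse);

    double l1 = 0.0;
    for (uword k = 0; k < K; ++k) l1 += pi(k) * norm(W.col(k), 1);
    const double pen_new = loglik - lambda * l1;
    trace.push_back(pen_new);

    // drop clusters that lost all responsibility
    const rowvec cs = sum(z, 0);
    uvec keep = find(cs.t() >= min_resp);
    if (keep.n_elem < K && keep.n_elem >= 1) {
      n_dropped += static_cast<int>(K - keep.n_elem);
      z = z.cols(keep);
      W = W.cols(keep);
      SSE = SSE.cols(keep);
      K = keep.n_elem;
      z.each_col() /= sum(z, 1);
      pen_ll = pen_new;
      continue; // objective not comparable across K; restart convergence check
    }

    if (iter > 0 && std::abs(pen_new - pen_ll) <
                        tol * (std::abs(pen_ll) + 1.0)) {
      pen_ll = pen_new;
      converged = true;
      break;
    }
    pen_ll = pen_new;
  }

  double entropy = 0.0;
  for (uword n = 0; n < z.n_rows; ++n)
    for (uword k = 0; k < K; ++k)
      if (z(n, k) > 0.0) entropy -= z(n, k) * std::log(z(n, k));

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("pi") = pi,
      Rcpp::Named("sigma2") = sigma2, Rcpp::Named("z") = z,
      Rcpp::Named("loglik") = loglik, Rcpp::Named("loglik_pen") = pen_ll,
      Rcpp::Named("entropy") = entropy, Rcpp::Named("K") = (int)K,
      Rcpp::Named("n_iter") = (int)trace.size(),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_dropped") = n_dropped,
      Rcpp::Named("n_obs") = (double)P, Rcpp::Named("trace") = trace);
}
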