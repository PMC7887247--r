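#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pseudo-likelihood gradient ascent for the pairwise maximum entropy model in
// the {-1,+1} convention. S is T x N with entries in {-1,+1}. Model moments use
// the tanh form of the single-site conditional; the J gradient is symmetrised
// each step so J stays symmetric throughout. The learning rate adapts: it grows
// geometrically while the moment error shrinks and backs off on oscillation.
// [[Rcpp::export]]
List cpp_pl_fit(const arma::mat& S, double eps0, double tol, int max_iter) {
  const int T = S.n_rows, N = S.n_cols;
  const double clip = 1.0 - 1.0 / (2.0 * T);

  arma::vec emp_m = arma::mean(S, 0).t();
  arma::mat emp_C = (S.t() * S) / double(T);
  emp_m = arma::clamp(emp_m, -clip, clip);
  emp_C = arma::clamp(emp_C, -clip, clip);

  arma::vec h(N, arma::fill::zeros);
  arma::mat J(N, N, arma::fill::zeros);

  double eps = eps0, prev_err = arma::datum::inf, err = arma::datum::inf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    arma::mat F = S * J;
    F.each_row() += h.t();
    arma::mat TH = arma::tanh(F);

    arma::vec model_m = arma::mean(TH, 0).t();
    arma::mat model_C = (TH.t() * S) / double(T);

    arma::vec Gh = emp_m - model_m;
    arma::mat GJ = emp_C - model_C;
    GJ = (GJ + GJ.t()) / 2.0;
    GJ.diag().zeros();

    err = std::max(arma::abs(Gh).max(), arma::abs(GJ).max());
    if (err < tol) break;

    if (err > prev_err) {
      eps = std::max(eps * 0.7, eps0 * 1e-3);
    } else {
      eps = std::min(eps * 1.02, eps0 * 40.0);
    }
    prev_err = err;

    h += eps * Gh;
    J += eps * GJ;
  }

  return List::create(_["h"] = h, _["J"] = J,
                      _["iterations"] = it,
                      _["max_moment_error"] = err,
                      _["converged"] = err < tol,
                      _["learning_rate_final"] = eps);
}

// Single-site Metropolis-Hastings sampler for the {0,1}-convention model.
// Energy E = -h.s - 0.5 s'Js; flipping site i changes E by -(h_i + sum_j J_ij
// s_j) * (1 - 2 s_i). One sweep = N proposals at uniformly random sites. Uses
// R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_metropolis(const arma::vec& h, const arma::mat& J,
                             int n_keep, int burn_in, int thin) {
  const int N = h.n_elem;
  arma::ivec s(N);
  for (int i = 0; i < N; ++i) s[i] = (unif_rand() < 0.5) ? 1 : 0;

  // local fields f_i = h_i + sum_j J_ij s_j, updated incrementally
  arma::vec f = h;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) f[i] += J(i, j) * s[j];

  IntegerMatrix out(n_keep, N);
  const long total_sweeps = (long)burn_in + (long)n_keep * thin;
  int kept = 0;
  for (long sw = 0; sw < total_sweeps && kept < n_keep; ++sw) {
    for (int p = 0; p < N; ++p) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      double ds = 1.0 - 2.0 * s[i];       // +1 if flipping 0->1, -1 if 1->0
      double dE = -f[i] * ds;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        s[i] = 1 - s[i];
        for (int j = 0; j < N; ++j) f[j] += J(j, i) * ds;
      }
    }
    if (sw >= burn_in && ((sw - burn_in) % thin == 0)) {
      for (int j = 0; j < N; ++j) out(kept, j) = s[j];
      ++kept;
    }
  }
  return out;
}

// Greedy distance-profile matching for the geometric structural null. Given
// the atlas distance matrix, the empirical (recorded-region) distance matrix
// and a seeded first pair on each side, iteratively pick the (empirical
// region, unused atlas region) pair whose distances to all previously matched
// regions agree best in L1. Returns 1-based index vectors ordered so that
// matched_emp[k] corresponds to matched_null[k].
// [[Rcpp::export]]
List cpp_geometric_null(const arma::mat& D_atlas, const arma::mat& D_emp,
                        int emp_a, int emp_b, int null_a, int null_b) {
  const int M = D_atlas.n_rows, n = D_emp.n_rows;

  std::vector<int> matched_emp, matched_null;
  matched_emp.reserve(n); matched_null.reserve(n);
  std::vector<bool> emp_used(n, false), null_used(M, false);

  matched_emp.push_back(emp_a);  matched_null.push_back(null_a);
  matched_emp.push_back(emp_b);  matched_null.push_back(null_b);
  emp_used[emp_a] = emp_used[emp_b] = true;
  null_used[null_a] = null_used[null_b] = true;

  while ((int)matched_emp.size() < n) {
    const int k = matched_emp.size();
    double best = arma::datum::inf;
    int best_e = -1, best_c = -1;
    for (int e = 0; e < n; ++e) {
      if (emp_used[e]) continue;
      for (int c = 0; c < M; ++c) {
        if (null_used[c]) continue;
        double cost = 0.0;
        for (int m = 0; m < k; ++m) {
          cost += std::abs(D_atlas(c, matched_null[m]) - D_emp(e, matched_emp[m]));
          if (cost >= best) break;
        }
        if (cost < best) { best = cost; best_e = e; best_c = c; }
      }
    }
    if (best_e < 0) stop("geometric null: candidate pool exhausted");
    matched_emp.push_back(best_e);
    matched_null.push_back(best_c);
    emp_used[best_e] = true;
    null_used[best_c] = true;
  }

  IntegerVector me(n), mn(n);
  for (int k = 0; k < n; ++k) { me[k] = matched_emp[k] + 1; mn[k] = matched_null[k] + 1; }
  return List::create(_["matched_emp"] = me, _["matched_null"] = mn);
}
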