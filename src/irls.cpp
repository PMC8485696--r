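// Logistic-regression IRLS core used by fitLogistic() and the
// interval/region model search. The search evaluates thousands of candidate
// region subsets, each with B bootstrap refits, so the bootstrap path is
// batched: all B refits of one candidate advance together through Newton
// steps expressed as dense matrix products, warm-started from the
// full-data fit, with converged refits dropped from subsequent sweeps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double ETA_CLAMP = 30.0;
static const int MAX_D = 16;   // intercept + up to 15 regions per candidate

// Cholesky solve of a d x d SPD system held in packed upper-triangular
// order (row-major j <= k), entirely on the stack. Returns false if a
// pivot collapses.
static bool chol_solve_packed(const double* mpack, const double* rhs,
                              double* x, int d) {
  double L[MAX_D][MAX_D];
  // unpack to full
  {
    int c = 0;
    for (int j = 0; j < d; ++j)
      for (int k = j; k < d; ++k, ++c) {
        L[j][k] = mpack[c];
        L[k][j] = mpack[c];
      }
  }
  // in-place lower Cholesky
  for (int j = 0; j < d; ++j) {
    double s = L[j][j];
    for (int k = 0; k < j; ++k) s -= L[j][k] * L[j][k];
    if (s <= 0.0) return false;
    const double piv = std::sqrt(s);
    L[j][j] = piv;
    for (int i = j + 1; i < d; ++i) {
      double t = L[i][j];
      for (int k = 0; k < j; ++k) t -= L[i][k] * L[j][k];
      L[i][j] = t / piv;
    }
  }
  // forward then backward substitution
  double ybuf[MAX_D];
  for (int i = 0; i < d; ++i) {
    double t = rhs[i];
    for (int k = 0; k < i; ++k) t -= L[i][k] * ybuf[k];
    ybuf[i] = t / L[i][i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double t = ybuf[i];
    for (int k = i + 1; k < d; ++k) t -= L[k][i] * x[k];
    x[i] = t / L[i][i];
  }
  return true;
}

// One logistic fit by Newton-Raphson. X includes the intercept column.
// lambda penalises all columns except the first (intercept).
static bool irls_fit(const mat& X, const vec& y, double lambda,
                     double tol, int maxit, vec& beta, int& iters) {
  const uword d = X.n_cols;
  vec pen(d, fill::value(lambda));
  pen(0) = 0.0;
  if (beta.n_elem != d) beta = zeros<vec>(d);
  for (iters = 0; iters < maxit; ++iters) {
    vec eta = X * beta;
    vec p = 1.0 / (1.0 + exp(-clamp(eta, -ETA_CLAMP, ETA_CLAMP)));
    vec w = p % (1.0 - p);
    mat M = X.t() * (X.each_col() % w);
    M.diag() += pen + 1e-10;
    vec g = X.t() * (y - p) - pen % beta;
    vec delta;
    if (!solve(delta, M, g, solve_opts::likely_sympd)) return false;
    beta += delta;
    if (abs(delta).max() < tol) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".logisticIRLS")]]
Rcpp::List logistic_irls_cpp(const arma::mat& X, const arma::vec& y,
                             double lambda = 0.0, double tol = 1e-8,
                             int maxit = 50) {
  vec beta = zeros<vec>(X.n_cols);
  int iters = 0;
  bool conv = irls_fit(X, y, lambda, tol, maxit, beta, iters);
  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}

// Bootstrap out-of-bag accuracy for a set of candidate region subsets that
// share one feature matrix (one time interval). `cnt` holds resample
// multiplicities (n x B), drawn in R so that all randomness flows through
// R's RNG.
//
// Returns per-subset mean OOB accuracy, the full B-vector of accuracies,
// fitted full-data coefficients, and the count of repetitions with an
// empty out-of-bag set (excluded from the mean).
// [[Rcpp::export(name = ".bootCandidates")]]
Rcpp::List boot_candidates_cpp(const arma::mat& X, const arma::vec& y,
                               const Rcpp::List& subsets,
                               const arma::mat& cnt,
                               double boot_lambda = 1e-6,
                               double boot_tol = 1e-4, int boot_maxit = 12,
                               double sep_lambda = 1.0) {
  const uword n = X.n_rows, B = cnt.n_cols;
  const uword S = subsets.size();
  if (y.n_elem != n || cnt.n_rows != n)
    Rcpp::stop("dimension mismatch between features, labels and resamples");

  vec acc_mean(S);
  mat accs(S, B, fill::value(datum::nan));
  Rcpp::List coef_out(S);
  ivec oob_empty(S, fill::zeros), ridge_used(S, fill::zeros);

  for (uword s = 0; s < S; ++s) {
    uvec idx = Rcpp::as<uvec>(subsets[s]);  // 0-based columns of X
    const uword d = idx.n_elem + 1;
    if (d > (uword)MAX_D) Rcpp::stop("candidate subset too large");
    mat Xs(n, d);
    Xs.col(0).ones();
    Xs.cols(1, d - 1) = X.cols(idx);

    // full-data fit; ridge fallback under (quasi-)separation
    vec beta_full = zeros<vec>(d);
    int it = 0;
    bool conv = irls_fit(Xs, y, 0.0, 1e-8, 40, beta_full, it);
    if (!conv || abs(beta_full).max() > ETA_CLAMP) {
      beta_full.zeros();
      irls_fit(Xs, y, sep_lambda, 1e-8, 60, beta_full, it);
      ridge_used(s) = 1;
    }

    mat Beta = repmat(beta_full, 1, B);

    // columns of Qmat are elementwise products x_j % x_k for j <= k, so
    // X'WX for all active resamples is one dense product Qmat' * W
    const uword dd = d * (d + 1) / 2;
    mat Qmat(n, dd);
    {
      uword c = 0;
      for (uword j = 0; j < d; ++j)
        for (uword k = j; k < d; ++k, ++c)
          Qmat.col(c) = Xs.col(j) % Xs.col(k);
    }

    uvec active = regspace<uvec>(0, B - 1);
    mat cntA = cnt;                        // columns tracked by `active`
    mat W(n, B), R(n, B);                  // reused buffers
    const double* yp = y.memptr();

    for (int iter = 0; iter < boot_maxit && active.n_elem > 0; ++iter) {
      const uword na = active.n_elem;
      mat ETA = Xs * Beta.cols(active);    // n x na
      // fused pass: sigmoid, IRLS weights, score residuals
      for (uword j = 0; j < na; ++j) {
        const double* cj = cntA.colptr(j);
        const double* ej = ETA.colptr(j);
        double* wj = W.colptr(j);
        double* rj = R.colptr(j);
        for (uword i = 0; i < n; ++i) {
          double e = ej[i];
          if (e > ETA_CLAMP) e = ETA_CLAMP;
          else if (e < -ETA_CLAMP) e = -ETA_CLAMP;
          const double p = 1.0 / (1.0 + std::exp(-e));
          wj[i] = cj[i] * p * (1.0 - p);
          rj[i] = cj[i] * (yp[i] - p);
        }
      }
      mat RHS = Xs.t() * R.cols(0, na - 1);      // d x na
      mat Mflat = Qmat.t() * W.cols(0, na - 1);  // dd x na
      std::vector<uword> still;
      still.reserve(na);
      double mp[MAX_D * (MAX_D + 1) / 2], rhs[MAX_D], delta[MAX_D];
      for (uword j = 0; j < na; ++j) {
        const uword b = active(j);
        {
          const double* mf = Mflat.colptr(j);
          uword c = 0;
          for (uword jj = 0; jj < d; ++jj)
            for (uword kk = jj; kk < d; ++kk, ++c)
              mp[c] = mf[c] + (jj == kk ? boot_lambda : 0.0);
        }
        for (uword jj = 0; jj < d; ++jj)
          rhs[jj] = RHS(jj, j) - boot_lambda * Beta(jj, b);
        bool ok = chol_solve_packed(mp, rhs, delta, (int)d);
        double md = 0.0;
        if (ok) {
          for (uword jj = 0; jj < d; ++jj) {
            double dj = delta[jj];
            if (dj > 10.0) dj = 10.0;      // guard rare wild steps
            else if (dj < -10.0) dj = -10.0;
            Beta(jj, b) += dj;
            const double a = std::fabs(dj);
            if (a > md) md = a;
          }
        } else {
          // collapsed pivot: freeze this refit at its current state
          md = 0.0;
        }
        if (md >= boot_tol && iter + 1 < boot_maxit)
          still.push_back(b);
      }
      if (still.size() == (size_t)na) continue;  // nothing converged
      active = uvec(still);
      if (active.n_elem > 0) cntA = cnt.cols(active);
    }

    // out-of-bag accuracy from the final linear predictors
    mat ETA = Xs * Beta;
    double asum = 0.0;
    uword acount = 0;
    for (uword b = 0; b < B; ++b) {
      const double* cj = cnt.colptr(b);
      const double* ej = ETA.colptr(b);
      uword noob = 0, correct = 0;
      for (uword i = 0; i < n; ++i) {
        if (cj[i] == 0.0) {
          ++noob;
          if ((ej[i] > 0.0) == (yp[i] > 0.5)) ++correct;
        }
      }
      if (noob == 0) {
        oob_empty(s) += 1;
      } else {
        const double a = double(correct) / double(noob);
        accs(s, b) = a;
        asum += a;
        ++acount;
      }
    }
    acc_mean(s) = acount ? asum / double(acount) : datum::nan;
    coef_out[s] = Rcpp::wrap(beta_full);
  }

  return Rcpp::List::create(
      Rcpp::Named("meanAccuracy") = acc_mean,
      Rcpp::Named("accuracies") = accs,
      Rcpp::Named("fullCoefficients") = coef_out,
      Rcpp::Named("ridgeFallback") = ridge_used,
      Rcpp::Named("emptyOOB") = oob_empty);
}
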