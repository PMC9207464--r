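// L1-penalized multinomial logistic regression with a pinned reference class.
//
// Minimizes, over intercepts b0 (unpenalized) and coefficients B:
//
//   -(1/N) sum_i sum_k tau_ik log pi_ik(b0, B)  +  lambda * sum_{k != ref} ||B_k||_1
//
// where pi_ik is the softmax of linear scores with the reference class score
// identically zero, and tau is a row-stochastic responsibility matrix (soft
// weights or one-hot labels).  Solved by proximal Newton: per-class quadratic
// approximation + coordinate descent, with sequential strong-rule screening
// and full KKT verification, warm-started along a decreasing lambda path.
//
// X is expected column-standardized by the caller; back-transformation to the
// original scale happens in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Softmax probabilities for the K-1 non-reference classes; the reference
// class has linear score 0.  S, P are N x (K-1).
static void pinned_softmax(const mat& S, mat& P) {
  const uword n = S.n_rows, km1 = S.n_cols;
  for (uword i = 0; i < n; ++i) {
    double m = 0.0;
    for (uword k = 0; k < km1; ++k) if (S(i, k) > m) m = S(i, k);
    double denom = std::exp(-m);
    for (uword k = 0; k < km1; ++k) denom += std::exp(S(i, k) - m);
    for (uword k = 0; k < km1; ++k) P(i, k) = std::exp(S(i, k) - m) / denom;
  }
}

static const double WMIN = 1e-5;   // lower clamp on IRLS weights
static const double KKT_EPS = 1e-7;

// When `restrict_cand` is true, the optimization is confined to the
// coefficients flagged in `cand_mask` (p x (K-1)); screening and KKT
// expansion are skipped.  Used for the post-selection unpenalized refit,
// which must not alter the selected support.
// [[Rcpp::export]]
Rcpp::List cpp_multinom_lasso_path(const arma::mat& X,
                                   const arma::mat& Tm,   // N x (K-1), non-reference tau columns
                                   const arma::vec& lambda,
                                   const arma::vec& b0_init,
                                   int maxit_outer,
                                   int maxit_cd,
                                   double tol,
                                   int dfmax,
                                   const arma::umat& cand_mask,
                                   bool restrict_cand,
                                   double coef_cap) {
  const uword n = X.n_rows, p = X.n_cols, km1 = Tm.n_cols;
  const uword nlam = lambda.n_elem;
  const double dn = static_cast<double>(n);

  mat B(p, km1, fill::zeros);
  vec b0 = b0_init;
  mat S(n, km1);
  for (uword k = 0; k < km1; ++k) S.col(k).fill(b0(k));
  mat P(n, km1);
  pinned_softmax(S, P);
  mat G = X.t() * (P - Tm) / dn;   // gradient wrt B, valid at current solution

  cube beta_path(p, km1, nlam, fill::zeros);
  mat b0_path(km1, nlam, fill::zeros);
  ivec df_path(nlam, fill::zeros);
  ivec iters(nlam, fill::zeros);
  ivec conv(nlam, fill::zeros);
  int nlam_used = 0;

  // deviance bookkeeping for early path termination (saturated-fit stop,
  // as is standard for regularization paths): mean weighted log-likelihood
  // sum_i sum_k tau_ik log pi_ik / N, with the reference class included
  auto mean_loglik = [&](const mat& Pm) {
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      double pref = 1.0;
      for (uword k = 0; k < km1; ++k) pref -= Pm(i, k);
      if (pref < 1e-12) pref = 1e-12;
      double tref = 1.0;
      for (uword k = 0; k < km1; ++k) {
        tref -= Tm(i, k);
        double pik = Pm(i, k) < 1e-12 ? 1e-12 : Pm(i, k);
        if (Tm(i, k) > 0) ll += Tm(i, k) * std::log(pik);
      }
      if (tref > 0) ll += tref * std::log(pref);
    }
    return ll / dn;
  };
  double ll_sat = 0.0;   // saturated fit: pi = tau
  for (uword i = 0; i < n; ++i) {
    double tref = 1.0;
    for (uword k = 0; k < km1; ++k) {
      tref -= Tm(i, k);
      if (Tm(i, k) > 0) ll_sat += Tm(i, k) * std::log(Tm(i, k));
    }
    if (tref > 1e-12) ll_sat += tref * std::log(tref);
  }
  ll_sat /= dn;
  const double ll_null = mean_loglik(P);
  double ll_prev = ll_null;

  std::vector<std::vector<uword>> cand(km1);
  std::vector<std::vector<char>> in_cand(km1, std::vector<char>(p, 0));
  if (restrict_cand) {
    for (uword k = 0; k < km1; ++k) {
      for (uword j = 0; j < p; ++j) {
        if (cand_mask(j, k)) { in_cand[k][j] = 1; cand[k].push_back(j); }
      }
    }
  }

  vec w(n), r(n), xwx(p);

  double lam_prev = lambda(0);
  for (uword m = 0; m < nlam; ++m) {
    const double lam = lambda(m);
    // sequential strong rule: keep current nonzeros, add strong candidates
    const double strong = 2.0 * lam - lam_prev;
    if (!restrict_cand) {
      for (uword k = 0; k < km1; ++k) {
        for (uword j = 0; j < p; ++j) {
          if (!in_cand[k][j] && (B(j, k) != 0.0 || std::abs(G(j, k)) >= strong)) {
            in_cand[k][j] = 1;
            cand[k].push_back(j);
          }
        }
      }
    }

    bool done = false;
    bool capped = false;
    int outer_total = 0;
    while (!done) {
      // proximal-Newton cycles over classes on the candidate set
      for (int it = 0; it < maxit_outer; ++it) {
        ++outer_total;
        double dmax = 0.0;
        for (uword k = 0; k < km1; ++k) {
          // quadratic approximation for class k at current probabilities
          for (uword i = 0; i < n; ++i) {
            double wi = P(i, k) * (1.0 - P(i, k));
            if (wi < WMIN) wi = WMIN;
            w(i) = wi;
            r(i) = (Tm(i, k) - P(i, k)) / wi;   // working residual at current fit
          }
          const double* wp = w.memptr();
          double* rp = r.memptr();
          for (uword c = 0; c < cand[k].size(); ++c) {
            uword j = cand[k][c];
            const double* xj = X.colptr(j);
            double s = 0.0;
            for (uword i = 0; i < n; ++i) s += wp[i] * xj[i] * xj[i];
            xwx(j) = s / dn;
          }
          const double wsum = accu(w);
          // coordinate descent (w, z fixed)
          for (int cd = 0; cd < maxit_cd; ++cd) {
            double dcd = 0.0;
            double num = 0.0;
            for (uword i = 0; i < n; ++i) num += wp[i] * rp[i];
            double d0 = num / wsum;
            if (d0 != 0.0) {
              b0(k) += d0;
              for (uword i = 0; i < n; ++i) rp[i] -= d0;
              double chg = (wsum / dn) * d0 * d0;
              if (chg > dcd) dcd = chg;
              if (chg > dmax) dmax = chg;
            }
            for (uword c = 0; c < cand[k].size(); ++c) {
              uword j = cand[k][c];
              double bj = B(j, k);
              const double* xj = X.colptr(j);
              double g = 0.0;
              for (uword i = 0; i < n; ++i) g += wp[i] * rp[i] * xj[i];
              g = g / dn + xwx(j) * bj;
              double bnew = soft_threshold(g, lam) / xwx(j);
              if (bnew != bj) {
                double d = bnew - bj;
                for (uword i = 0; i < n; ++i) rp[i] -= d * xj[i];
                B(j, k) = bnew;
                double chg = xwx(j) * d * d;
                if (chg > dcd) dcd = chg;
                if (chg > dmax) dmax = chg;
              }
            }
            if (dcd < tol) break;
          }
          // refresh scores for class k from the working fit: s = z - r,
          // where z was s_old + (tau - p)/w
          for (uword i = 0; i < n; ++i) {
            double z = S(i, k) + (Tm(i, k) - P(i, k)) / w(i);
            S(i, k) = z - r(i);
          }
          pinned_softmax(S, P);
        }
        if (abs(B).max() > coef_cap || abs(b0).max() > coef_cap) {
          capped = true;   // separable direction: stop growing the path
          break;
        }
        if (dmax < tol) { conv(m) = 1; break; }
      }
      if (capped) break;
      // full KKT check; gradient then certifies the solution and feeds the
      // next lambda's strong rule
      if (restrict_cand) { done = true; break; }
      G = X.t() * (P - Tm) / dn;
      uword viol = 0;
      for (uword k = 0; k < km1; ++k) {
        for (uword j = 0; j < p; ++j) {
          if (!in_cand[k][j] && std::abs(G(j, k)) > lam + KKT_EPS) {
            in_cand[k][j] = 1;
            cand[k].push_back(j);
            ++viol;
          }
        }
      }
      if (viol == 0) done = true;
    }

    beta_path.slice(m) = B;
    b0_path.col(m) = b0;
    uvec nz = find(abs(vectorise(B)) > 0.0);
    df_path(m) = static_cast<int>(nz.n_elem);
    iters(m) = outer_total;
    nlam_used = static_cast<int>(m) + 1;
    lam_prev = lam;
    if (capped || df_path(m) > dfmax) break;
    // stop once the fit is essentially saturated or no longer improving
    const double ll_m = mean_loglik(P);
    const double denom = ll_sat - ll_null;
    if (denom > 0) {
      const double dev_ratio = (ll_m - ll_null) / denom;
      const double dev_step = (ll_m - ll_prev) / denom;
      if (m > 0 && (dev_ratio > 0.999 || (df_path(m) > 0 && dev_step < 1e-5)))
        break;
    }
    ll_prev = ll_m;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_path,
    Rcpp::Named("b0") = b0_path,
    Rcpp::Named("df") = df_path,
    Rcpp::Named("iters") = iters,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("nlambda_used") = nlam_used);
}
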