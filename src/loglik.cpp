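// Marginal likelihood kernels for the multivariate mixed cumulative logit
// model. Observations enter as "cells" (subject x occasion x outcome with a
// non-missing category): each cell carries the fixed parts of the two
// cumulative logits bracketing its category (+/-Inf at the scale ends) and
// the w-columns of its outcome's random intercept/slope. The conditional
// category probability at random effect w is F(eta_up + z'w) - F(eta_lo +
// z'w) with F the logistic cdf; z'w = w[icol] + t * w[scol].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PFLOOR = 1e-10;

static inline double plogis_(double x) {
  if (x > 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// category probability and (optionally) cdf values at the two bounds
static inline double cellprob(double up, double lo, double &Fu, double &Fl) {
  Fu = std::isinf(up) ? 1.0 : plogis_(up);
  Fl = std::isinf(lo) ? 0.0 : plogis_(lo);
  return Fu - Fl;
}

// Marginal log-likelihood under a fixed point rule: points W (Q x dW) in
// random-effect space with log-weights logwt such that
// P_i = sum_q exp(logwt_q) * prod_cells p(cell | w_q).
// Optionally returns the exact gradient pieces of the rule's approximation:
// A_up/A_lo are posterior-weighted d log p / d eta sums per cell, G_W the
// gradient with respect to the point coordinates (chained to the Cholesky
// factor on the R side).
// Wt holds the points transposed (dW x Q) so each point's coordinates are
// contiguous. G_W is returned as dW x Q; the caller chains G_L = G_W M.
// [[Rcpp::export]]
List cpp_marginal_loglik(NumericVector eta_up, NumericVector eta_lo,
                         NumericVector tt, IntegerVector subj,
                         IntegerVector icol, IntegerVector scol,
                         arma::mat Wt, NumericVector logwt,
                         int nsubj, bool want_grad) {
  const int ncell = eta_up.size();
  const int Q = Wt.n_cols;
  const int dW = Wt.n_rows;
  const double *pu = eta_up.begin(), *pl = eta_lo.begin(),
               *pt = tt.begin(), *plw = logwt.begin();
  const int *ps = subj.begin(), *pic = icol.begin(), *psc = scol.begin();

  arma::mat cll(nsubj, Q, arma::fill::zeros);
  arma::mat DU, DL;  // per cell x point d log p / d eta, kept for pass 2
  if (want_grad) {
    DU.set_size(ncell, Q);
    DL.set_size(ncell, Q);
  }
  for (int q = 0; q < Q; ++q) {
    const double *w = Wt.colptr(q);
    double *cq = cll.colptr(q);
    double *duq = want_grad ? DU.colptr(q) : nullptr;
    double *dlq = want_grad ? DL.colptr(q) : nullptr;
    for (int m = 0; m < ncell; ++m) {
      double o = 0.0;
      if (pic[m] >= 0) o += w[pic[m]];
      if (psc[m] >= 0) o += w[psc[m]] * pt[m];
      double Fu, Fl;
      double p = cellprob(pu[m] + o, pl[m] + o, Fu, Fl);
      bool floored = p < PFLOOR;
      if (floored) p = PFLOOR;
      cq[ps[m]] += std::log(p);
      if (want_grad) {
        if (floored) {
          duq[m] = dlq[m] = 0.0;  // floored cells are locally constant
        } else {
          duq[m] = std::isinf(pu[m]) ? 0.0 : Fu * (1.0 - Fu) / p;
          dlq[m] = std::isinf(pl[m]) ? 0.0 : -Fl * (1.0 - Fl) / p;
        }
      }
    }
  }

  NumericVector lls(nsubj);
  double *plls = lls.begin();
  for (int i = 0; i < nsubj; ++i) plls[i] = R_NegInf;
  for (int q = 0; q < Q; ++q) {
    const double *cq = cll.colptr(q);
    for (int i = 0; i < nsubj; ++i) {
      double v = plw[q] + cq[i];
      if (v > plls[i]) plls[i] = v;
    }
  }
  std::vector<double> acc(nsubj, 0.0);
  for (int q = 0; q < Q; ++q) {
    const double *cq = cll.colptr(q);
    for (int i = 0; i < nsubj; ++i)
      acc[i] += std::exp(plw[q] + cq[i] - plls[i]);
  }
  double total = 0.0;
  for (int i = 0; i < nsubj; ++i) {
    plls[i] += std::log(acc[i]);
    total += plls[i];
  }

  if (!want_grad) {
    return List::create(_["ll"] = total, _["ll_subject"] = lls);
  }

  // overwrite cll with the posterior point weights r_iq, then sweep the
  // stored derivatives once
  NumericVector A_up(ncell), A_lo(ncell);
  double *au = A_up.begin(), *al = A_lo.begin();
  arma::mat G_W(dW, Q, arma::fill::zeros);
  for (int q = 0; q < Q; ++q) {
    double *cq = cll.colptr(q);
    for (int i = 0; i < nsubj; ++i)
      cq[i] = std::exp(plw[q] + cq[i] - plls[i]);
    const double *duq = DU.colptr(q), *dlq = DL.colptr(q);
    double *gw = G_W.colptr(q);
    for (int m = 0; m < ncell; ++m) {
      double wgt = cq[ps[m]];
      double du = wgt * duq[m], dl = wgt * dlq[m];
      au[m] += du;
      al[m] += dl;
      double g = du + dl;
      if (pic[m] >= 0) gw[pic[m]] += g;
      if (psc[m] >= 0) gw[psc[m]] += g * pt[m];
    }
  }
  return List::create(_["ll"] = total, _["ll_subject"] = lls,
                      _["A_up"] = A_up, _["A_lo"] = A_lo, _["G_W"] = G_W);
}

// Adaptive Gauss-Hermite marginal log-likelihood: per subject the integrand
// h(w) = conditional loglik + log MVN(0, Sigma) density is maximized by
// damped Newton (analytic gradient and Hessian), the quadrature grid is
// recentred at the mode and rescaled by the Cholesky factor of the inverse
// negative Hessian, and the integral is accumulated by log-sum-exp. U holds
// the standardized product-rule abscissae (Q x d), loglam their log product
// weights. Subjects whose Newton iteration fails fall back to prior
// centering (mode 0, scale chol(Sigma)) and are counted in n_fallback.
// [[Rcpp::export]]
List cpp_agh_loglik(NumericVector eta_up, NumericVector eta_lo,
                    NumericVector tt, IntegerVector subj,
                    IntegerVector icol, IntegerVector scol,
                    arma::mat Sigma, arma::mat U, NumericVector loglam,
                    int nsubj, int maxit, double tol) {
  const int ncell = eta_up.size();
  const int Q = U.n_rows;
  const int d = Sigma.n_rows;

  std::vector<std::vector<int>> bysubj(nsubj);
  for (int m = 0; m < ncell; ++m) bysubj[subj[m]].push_back(m);

  arma::mat Om = arma::inv_sympd(Sigma);
  double ldS;
  {
    double sign;
    arma::log_det(ldS, sign, Sigma);
  }
  const double cphi = -0.5 * d * std::log(2.0 * M_PI) - 0.5 * ldS;
  const double sqrt2 = std::sqrt(2.0);

  // h, gradient, Hessian of the log integrand at w for one subject
  auto eval_h = [&](const std::vector<int> &cells, const arma::vec &w,
                    arma::vec *g, arma::mat *H) -> double {
    double h = cphi - 0.5 * arma::dot(w, Om * w);
    if (g) *g = -Om * w;
    if (H) *H = -Om;
    for (int m : cells) {
      double o = 0.0;
      if (icol[m] >= 0) o += w(icol[m]);
      if (scol[m] >= 0) o += w(scol[m]) * tt[m];
      double Fu, Fl;
      double p = cellprob(eta_up[m] + o, eta_lo[m] + o, Fu, Fl);
      if (p < PFLOOR) p = PFLOOR;
      h += std::log(p);
      if (g) {
        double fu = std::isinf(eta_up[m]) ? 0.0 : Fu * (1.0 - Fu);
        double fl = std::isinf(eta_lo[m]) ? 0.0 : Fl * (1.0 - Fl);
        double gc = (fu - fl) / p;
        double dfu = std::isinf(eta_up[m]) ? 0.0 : fu * (1.0 - 2.0 * Fu);
        double dfl = std::isinf(eta_lo[m]) ? 0.0 : fl * (1.0 - 2.0 * Fl);
        double hc = (dfu - dfl) / p - gc * gc;
        if (icol[m] >= 0) (*g)(icol[m]) += gc;
        if (scol[m] >= 0) (*g)(scol[m]) += gc * tt[m];
        if (H) {
          if (icol[m] >= 0) (*H)(icol[m], icol[m]) += hc;
          if (scol[m] >= 0) (*H)(scol[m], scol[m]) += hc * tt[m] * tt[m];
          if (icol[m] >= 0 && scol[m] >= 0) {
            (*H)(icol[m], scol[m]) += hc * tt[m];
            (*H)(scol[m], icol[m]) += hc * tt[m];
          }
        }
      }
    }
    return h;
  };

  NumericVector lls(nsubj);
  int nfail = 0;
  double total = 0.0;
  arma::mat Lp = arma::chol(Sigma, "lower");

  for (int i = 0; i < nsubj; ++i) {
    const std::vector<int> &cells = bysubj[i];
    arma::vec w(d, arma::fill::zeros), g(d);
    arma::mat H(d, d);
    double h = eval_h(cells, w, &g, &H);
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      if (arma::norm(g, "inf") < tol) { ok = true; break; }
      arma::vec step;
      bool solved = arma::solve(step, -H, g, arma::solve_opts::likely_sympd);
      if (!solved || !step.is_finite()) break;
      double lam = 1.0;
      bool improved = false;
      for (int half = 0; half < 30; ++half) {
        arma::vec wn = w + lam * step;
        double hn = eval_h(cells, wn, nullptr, nullptr);
        if (hn >= h - 1e-12) {
          w = wn; h = hn;
          improved = true;
          break;
        }
        lam *= 0.5;
      }
      if (!improved) break;
      h = eval_h(cells, w, &g, &H);
    }
    if (arma::norm(g, "inf") < tol) ok = true;

    arma::mat A;
    arma::vec mode = w;
    if (ok) {
      arma::mat Hn = -H;  // negative Hessian at the mode, positive definite
      arma::mat Hinv;
      if (arma::inv_sympd(Hinv, Hn)) {
        ok = arma::chol(A, Hinv, "lower");
      } else {
        ok = false;
      }
    }
    if (!ok) {
      ++nfail;
      mode.zeros();
      A = Lp;
    }

    double mx = R_NegInf;
    std::vector<double> vals(Q);
    for (int q = 0; q < Q; ++q) {
      arma::vec u = U.row(q).t();
      arma::vec wq = mode + sqrt2 * (A * u);
      double v = loglam[q] + arma::dot(u, u) +
                 eval_h(cells, wq, nullptr, nullptr);
      vals[q] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int q = 0; q < Q; ++q) s += std::exp(vals[q] - mx);
    lls[i] = 0.5 * d * std::log(2.0) + arma::accu(arma::log(A.diag())) +
             mx + std::log(s);
    total += lls[i];
  }

  return List::create(_["ll"] = total, _["ll_subject"] = lls,
                      _["n_fallback"] = nfail);
}
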