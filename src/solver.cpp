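// Compiled kernels: elastic-net coordinate descent along a regularization
// path (sequential strong rules + KKT rechecks + warm starts + optional
// validation-based early stopping), single-SNP association fits, and greedy
// LD clumping. Matrices are expected column-standardized where stated.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static inline double clamp_prob(double p) {
  const double eps = 1e-10;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

// Elastic-net CD path.
// X: n x p, columns standardized on these rows (mean 0, population var 1 for
//    penalized columns; unpenalized covariate columns standardized too).
// family: 0 = gaussian (squared error / 2), 1 = logistic.
// penalty_factor: 1 penalized, 0 unpenalized.
// Objective: (1/n) * loss + lambda * ((1-alpha)/2 ||b||_2^2 + alpha ||b||_1)
// over penalized coefficients.
// [[Rcpp::export]]
List cd_elnet_path(const arma::mat& X, const arma::vec& y, int family,
                   const arma::vec& lambdas, double alpha,
                   const arma::vec& penalty_factor,
                   const arma::mat& Xval, const arma::vec& yval, bool has_val,
                   int patience, double tol, int max_iter, bool use_strong,
                   int dfmax) {
  const int n = X.n_rows, p = X.n_cols, K = lambdas.n_elem;
  arma::vec beta(p, arma::fill::zeros);
  double beta0 = 0.0;

  arma::mat beta_path(p, K, arma::fill::zeros);
  arma::vec beta0_path(K, arma::fill::zeros);
  arma::vec val_loss(K);
  val_loss.fill(NA_REAL);

  // state for gaussian: residual r = y - beta0 - X*beta
  // state for logistic: linear predictor eta
  arma::vec r, eta;
  if (family == 0) {
    beta0 = arma::mean(y);
    r = y - beta0;
  } else {
    double ybar = arma::mean(y);
    beta0 = std::log(clamp_prob(ybar) / (1.0 - clamp_prob(ybar)));
    eta = arma::vec(n, arma::fill::value(beta0));
  }

  // full gradient |x_j' r|/n at the current solution (for strong rule + KKT)
  arma::vec grad(p, arma::fill::zeros);
  {
    arma::vec res = (family == 0) ? r : arma::vec(y - 1.0 / (1.0 + arma::exp(-eta)));
    grad = X.t() * res / n;
  }

  std::vector<bool> ever_active(p, false);
  int stopped_at = K;
  int best_k = -1;
  double best_loss = R_PosInf;
  long total_iter = 0;

  for (int k = 0; k < K; ++k) {
    const double lam = lambdas[k];
    const double lam_prev = (k == 0) ? lam : lambdas[k - 1];
    const double strong_thr = alpha * (2.0 * lam - lam_prev);

    // candidate set
    std::vector<int> cand;
    std::vector<bool> in_cand(p, false);
    for (int j = 0; j < p; ++j) {
      bool take = !use_strong || ever_active[j] || penalty_factor[j] == 0.0 ||
                  std::abs(grad[j]) >= strong_thr;
      if (take) { cand.push_back(j); in_cand[j] = true; }
    }

    bool kkt_ok = false;
    while (!kkt_ok) {
      if (family == 0) {
        // plain CD on the squared-error objective
        for (;;) {
          if (++total_iter > max_iter)
            stop("coordinate descent failed to converge at lambda = %g", lam);
          double maxdiff = 0.0;
          for (int j : cand) {
            const double vj = 1.0;  // standardized columns
            double u = arma::dot(X.col(j), r) / n + vj * beta[j];
            double pen = penalty_factor[j];
            double bnew = soft_threshold(u, lam * alpha * pen) /
                          (vj + lam * (1.0 - alpha) * pen);
            double d = bnew - beta[j];
            if (d != 0.0) {
              r -= X.col(j) * d;
              beta[j] = bnew;
              if (bnew != 0.0) ever_active[j] = true;
              maxdiff = std::max(maxdiff, std::abs(d));
            }
          }
          double d0 = arma::mean(r);
          if (d0 != 0.0) { beta0 += d0; r -= d0; maxdiff = std::max(maxdiff, std::abs(d0)); }
          if (maxdiff < tol) break;
        }
      } else {
        // IRLS outer loop with weighted CD inner loop
        for (int outer = 0; outer < 100; ++outer) {
          arma::vec prob = 1.0 / (1.0 + arma::exp(-eta));
          prob.transform([](double v) { return clamp_prob(v); });
          arma::vec w = prob % (1.0 - prob);
          arma::vec s = (y - prob) / w;  // working residual (z - eta)
          const double wsum = arma::accu(w);
          // curvature terms for current weights
          std::vector<double> vj(cand.size());
          for (size_t c = 0; c < cand.size(); ++c)
            vj[c] = arma::dot(w, arma::square(X.col(cand[c]))) / n;
          double outer_change = 0.0;
          for (;;) {
            if (++total_iter > max_iter)
              stop("coordinate descent failed to converge at lambda = %g", lam);
            double maxdiff = 0.0;
            for (size_t c = 0; c < cand.size(); ++c) {
              int j = cand[c];
              double u = arma::dot(X.col(j), w % s) / n + vj[c] * beta[j];
              double pen = penalty_factor[j];
              double bnew = soft_threshold(u, lam * alpha * pen) /
                            (vj[c] + lam * (1.0 - alpha) * pen);
              double d = bnew - beta[j];
              if (d != 0.0) {
                s -= X.col(j) * d;
                beta[j] = bnew;
                if (bnew != 0.0) ever_active[j] = true;
                maxdiff = std::max(maxdiff, std::abs(d));
              }
            }
            double d0 = arma::dot(w, s) / wsum;
            if (d0 != 0.0) { beta0 += d0; s -= d0; maxdiff = std::max(maxdiff, std::abs(d0)); }
            outer_change = std::max(outer_change, maxdiff);
            if (maxdiff < tol) break;
          }
          // eta implied by the quadratic solve: z - s, with z = eta + (y-p)/w
          eta = eta + (y - prob) / w - s;
          if (outer_change < tol) break;
        }
      }

      // full KKT check; re-admit violators
      arma::vec res = (family == 0) ? r : arma::vec(y - 1.0 / (1.0 + arma::exp(-eta)));
      grad = X.t() * res / n;
      kkt_ok = true;
      for (int j = 0; j < p; ++j) {
        if (!in_cand[j] && penalty_factor[j] > 0.0 && beta[j] == 0.0 &&
            std::abs(grad[j]) > lam * alpha + 1e-9) {
          cand.push_back(j); in_cand[j] = true; kkt_ok = false;
        }
      }
    }

    beta_path.col(k) = beta;
    beta0_path[k] = beta0;

    if (has_val) {
      double loss;
      if (family == 0) {
        arma::vec ev = yval - beta0 - Xval * beta;
        loss = 0.5 * arma::dot(ev, ev) / yval.n_elem;
      } else {
        arma::vec ev = beta0 + Xval * beta;
        arma::vec pv = 1.0 / (1.0 + arma::exp(-ev));
        pv.transform([](double v) { return clamp_prob(v); });
        loss = -arma::mean(yval % arma::log(pv) +
                           (1.0 - yval) % arma::log(1.0 - pv));
      }
      val_loss[k] = loss;
      if (loss < best_loss - 1e-12) { best_loss = loss; best_k = k; }
      if (k - best_k >= patience) { stopped_at = k + 1; break; }
    }

    // glmnet-style df cap: abandon the path once models grow denser than
    // requested (the saved points remain valid solutions)
    if (dfmax > 0) {
      int nnz = 0;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) ++nnz;
      if (nnz > dfmax) { stopped_at = k + 1; break; }
    }
  }

  int used = std::min(stopped_at, K);
  return List::create(
      _["beta0"] = beta0_path.head(used),
      _["beta"] = beta_path.cols(0, used - 1),
      _["lambda"] = lambdas.head(used),
      _["val_loss"] = val_loss.head(used),
      _["stopped_at"] = stopped_at,
      _["best_index"] = best_k + 1);
}

// Column standardization (x - m) / s done in one pass; zero-variance
// columns (s <= 0) come out as all-zero.
// [[Rcpp::export]]
arma::mat scale_columns(const arma::mat& X, const arma::vec& center,
                        const arma::vec& scale) {
  arma::mat out = X;
  out.each_row() -= center.t();
  arma::vec s = scale;
  s.transform([](double v) { return (v > 0.0) ? v : 1.0; });
  out.each_row() /= s.t();
  return out;
}

// Single-SNP association scans. C holds the intercept and any covariates.
// family 0 = linear (t-test), 1 = logistic (Wald, score-test fallback).
// [[Rcpp::export]]
List gwas_scan(const arma::mat& G, const arma::vec& y, const arma::mat& C,
               int family, const arma::vec& null_coef) {
  const int n = G.n_rows, p = G.n_cols, q = C.n_cols;
  arma::vec beta(p), se(p), z(p), pval(p);

  if (family == 0) {
    arma::mat CtC_inv = arma::inv_sympd(C.t() * C);
    arma::vec yr = y - C * (CtC_inv * (C.t() * y));
    const double yy = arma::dot(yr, yr);
    const int df = n - q - 1;
    for (int j = 0; j < p; ++j) {
      arma::vec g = G.col(j);
      arma::vec gr = g - C * (CtC_inv * (C.t() * g));
      double gg = arma::dot(gr, gr);
      if (gg < 1e-12) { beta[j] = 0; se[j] = R_PosInf; z[j] = 0; pval[j] = 1; continue; }
      double b = arma::dot(gr, yr) / gg;
      double rss = yy - b * b * gg;
      double sigma2 = std::max(rss, 0.0) / std::max(df, 1);
      double s = std::sqrt(sigma2 / gg);
      beta[j] = b; se[j] = s;
      if (s > 0) {
        z[j] = b / s;
        pval[j] = 2.0 * R::pt(-std::abs(z[j]), df, 1, 0);
      } else { z[j] = (b > 0) ? R_PosInf : R_NegInf; pval[j] = 0.0; }
      if (pval[j] <= 0) pval[j] = 2.2e-308;
    }
  } else {
    // null-model quantities for the score test
    arma::vec eta0 = C * null_coef;
    arma::vec p0 = 1.0 / (1.0 + arma::exp(-eta0));
    arma::vec w0 = p0 % (1.0 - p0);
    arma::mat CtW0C_inv = arma::inv_sympd(C.t() * (C.each_col() % w0));
    arma::vec y_p0 = y - p0;

    for (int j = 0; j < p; ++j) {
      arma::vec g = G.col(j);
      // Newton-Raphson on (covariates, SNP)
      arma::vec coef(q + 1, arma::fill::zeros);
      coef.head(q) = null_coef;
      bool ok = false;
      arma::mat H_inv;
      for (int it = 0; it < 30; ++it) {
        arma::vec eta = C * coef.head(q) + g * coef[q];
        arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
        arma::vec w = pr % (1.0 - pr);
        arma::vec resid = y - pr;
        arma::vec grad(q + 1);
        grad.head(q) = C.t() * resid;
        grad[q] = arma::dot(g, resid);
        arma::mat H(q + 1, q + 1);
        arma::mat CW = C.each_col() % w;
        H.submat(0, 0, q - 1, q - 1) = C.t() * CW;
        arma::vec gw = CW.t() * g;
        H.submat(0, q, q - 1, q) = gw;
        H.submat(q, 0, q, q - 1) = gw.t();
        H(q, q) = arma::dot(g, w % g);
        bool solved = arma::inv_sympd(H_inv, H);
        if (!solved) break;
        arma::vec step = H_inv * grad;
        coef += step;
        if (arma::norm(grad, "inf") < 1e-8 && arma::norm(step, "inf") < 1e-6) {
          ok = std::abs(coef[q]) < 15.0;
          break;
        }
      }
      if (ok) {
        double s = std::sqrt(H_inv(q, q));
        beta[j] = coef[q]; se[j] = s;
        z[j] = coef[q] / s;
        pval[j] = 2.0 * R::pnorm(-std::abs(z[j]), 0.0, 1.0, 1, 0);
      } else {
        // score test under the null (robust to separation)
        double u = arma::dot(g, y_p0);
        arma::vec cwg = C.t() * (w0 % g);
        double v = arma::dot(g, w0 % g) -
                   arma::as_scalar(cwg.t() * CtW0C_inv * cwg);
        double zz = (v > 0) ? u / std::sqrt(v) : 0.0;
        beta[j] = std::min(std::max(coef[q], -15.0), 15.0);
        z[j] = zz;
        se[j] = (std::abs(zz) > 1e-12) ? std::abs(beta[j] / zz) : R_PosInf;
        pval[j] = 2.0 * R::pnorm(-std::abs(zz), 0.0, 1.0, 1, 0);
      }
      if (pval[j] <= 0) pval[j] = 2.2e-308;
      if (pval[j] > 1) pval[j] = 1.0;
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["z"] = z,
                      _["p"] = pval);
}

// Greedy LD clumping. Variants must be ordered by (chromosome block,
// position). order_idx gives the clumping priority (0-based, best first).
// Returns 1-based kept indices (in keep order) and 1-based assignment map.
// [[Rcpp::export]]
List clump_greedy(const arma::mat& Xs,  // ld_rows x p, standardized columns
                  const IntegerVector& chrom, const NumericVector& pos,
                  const IntegerVector& order_idx,
                  double r2_threshold, double window_bp) {
  const int n = Xs.n_rows, p = Xs.n_cols;
  IntegerVector assigned(p, NA_INTEGER);
  std::vector<int> kept;
  for (int oi = 0; oi < p; ++oi) {
    int i = order_idx[oi];
    if (!IntegerVector::is_na(assigned[i])) continue;
    assigned[i] = i + 1;
    kept.push_back(i + 1);
    // scan contiguous window on the same chromosome
    for (int dir = -1; dir <= 1; dir += 2) {
      for (int j = i + dir; j >= 0 && j < p; j += dir) {
        if (chrom[j] != chrom[i]) break;
        if (std::abs(pos[j] - pos[i]) > window_bp) break;
        if (!IntegerVector::is_na(assigned[j])) continue;
        double r = arma::dot(Xs.col(i), Xs.col(j)) / n;
        if (r * r > r2_threshold) assigned[j] = i + 1;
      }
    }
  }
  return List::create(_["kept"] = wrap(kept), _["assigned"] = assigned);
}
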