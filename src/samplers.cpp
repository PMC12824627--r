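// Blocked Gibbs samplers for the joint latent-variable (multivariate probit)
// model and the logistic comparator model.
//
// ABBA: the latent variable y2* is updated by sign-constrained augmentation
// (positive where the observed binary indicator is 1, negative where it is
// 0), the six regression coefficients of each subtrial jointly from their
// conjugate multivariate normal full conditional given Sigma, hierarchical
// means conjugately, and the truncated-exponential hierarchical SDs, the
// outcome SD sigma1 and the latent correlation rho by univariate slice
// sampling.  All randomness goes through R's RNG so set.seed() governs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- utilities -----------------------------------------------------------

// X ~ N(m, s^2) truncated to (lo, Inf).
static double rtnorm_above(double m, double s, double lo)
{
  double a = (lo - m) / s;
  if (a < 4.0) {
    double p = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(p, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return m + s * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  // Robert (1995) exponential rejection for far tails.
  double alpha = (a + std::sqrt(a * a + 4.0)) / 2.0;
  for (;;) {
    double z = a + R::exp_rand() / alpha;
    double d = z - alpha;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return m + s * z;
  }
}

// X ~ N(m, s^2) truncated to (-Inf, hi).
static inline double rtnorm_below(double m, double s, double hi)
{
  return -rtnorm_above(-m, s, -hi);
}

// Univariate slice sampler (Neal 2003), stepping out + shrinkage, bounded.
template <typename F>
static double slice1(double x0, F logf, double w, double lb, double ub)
{
  double f0 = logf(x0);
  double y = f0 - R::exp_rand();
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int m = 50;
  int j = (int)std::floor(m * R::unif_rand());
  int k = m - 1 - j;
  if (L < lb) L = lb;
  if (Rr > ub) Rr = ub;
  while (j-- > 0 && L > lb && logf(L) > y) { L -= w; if (L < lb) L = lb; }
  while (k-- > 0 && Rr < ub && logf(Rr) > y) { Rr += w; if (Rr > ub) Rr = ub; }
  for (int it = 0; it < 200; it++) {
    double x1 = L + (Rr - L) * R::unif_rand();
    if (logf(x1) >= y) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

static arma::vec rmvnorm_prec(const arma::vec &rhs, const arma::mat &P)
{
  // Draw from N(P^{-1} rhs, P^{-1}).
  arma::mat U = arma::chol(P);                 // U'U = P
  arma::vec mu = arma::solve(arma::trimatu(U),
                 arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec z(rhs.n_elem);
  for (arma::uword i = 0; i < z.n_elem; i++) z[i] = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

// ---- ABBA ---------------------------------------------------------------

// Coefficient column layout (per subtrial): 0 beta1, 1 gamma1, 2 theta1,
// 3 beta2, 4 gamma2, 5 theta2.  Prior group of column j: j % 3
// (0 intercept, 1 baseline, 2 treatment).

// [[Rcpp::export]]
List abba_gibbs_cpp(NumericVector y1_, IntegerVector y2_, NumericVector lx_,
                    NumericVector t_, IntegerVector sub_, int K,
                    bool sharing, int n_chains, int n_warmup, int n_iter,
                    double sd_coef, double sd_treat_strat,
                    double sig1_shape, double sig1_scale,
                    double lkj_eta, double exp_rate, double trunc_lb)
{
  int N = y1_.size();
  arma::vec y1(y1_.begin(), N), lx(lx_.begin(), N), tt(t_.begin(), N);
  arma::ivec y2(N), sub(N);
  for (int i = 0; i < N; i++) { y2[i] = y2_[i]; sub[i] = sub_[i] - 1; }

  // Per-subtrial design cross-products (constant across iterations).
  std::vector<arma::mat> Sxx(K, arma::mat(3, 3, arma::fill::zeros));
  std::vector<arma::vec> Sxy1(K, arma::vec(3, arma::fill::zeros));
  std::vector<std::vector<int> > idx(K);
  for (int i = 0; i < N; i++) {
    arma::vec x = {1.0, lx[i], tt[i]};
    Sxx[sub[i]] += x * x.t();
    Sxy1[sub[i]] += x * y1[i];
    idx[sub[i]].push_back(i);
  }

  int P = K * 6 + (sharing ? 12 : 0) + 2;
  List chains(n_chains);

  for (int ch = 0; ch < n_chains; ch++) {
    // ---- initial state (chain-specific jitter) ----
    arma::mat coef(K, 6, arma::fill::zeros);
    for (int k = 0; k < K; k++) {
      arma::vec a1 = arma::solve(Sxx[k] + 1e-6 * arma::eye(3, 3), Sxy1[k]);
      coef(k, 0) = a1[0]; coef(k, 1) = a1[1]; coef(k, 2) = a1[2];
      for (int j = 0; j < 6; j++) coef(k, j) += 0.1 * R::norm_rand();
    }
    arma::vec hmu(6, arma::fill::zeros), hsd(6, arma::fill::ones);
    hsd *= 0.5;
    for (int j = 0; j < 6; j++) hmu[j] = arma::mean(coef.col(j));
    double sigma1 = std::max(0.1, arma::stddev(y1) * 0.7) *
                    std::exp(0.1 * R::norm_rand());
    double rho = 0.0;
    arma::vec ystar(N);
    for (int i = 0; i < N; i++) ystar[i] = y2[i] == 1 ? 0.5 : -0.5;

    arma::mat out(n_iter, P);
    int total = n_warmup + n_iter;

    for (int it = 0; it < total; it++) {
      // means
      arma::vec mu1(N), mu2(N);
      for (int i = 0; i < N; i++) {
        int k = sub[i];
        mu1[i] = coef(k, 0) + coef(k, 1) * lx[i] + coef(k, 2) * tt[i];
        mu2[i] = coef(k, 3) + coef(k, 4) * lx[i] + coef(k, 5) * tt[i];
      }

      // 1. latent variable, sign-constrained
      double csd = std::sqrt(1.0 - rho * rho);
      for (int i = 0; i < N; i++) {
        double cm = mu2[i] + rho * (y1[i] - mu1[i]) / sigma1;
        ystar[i] = y2[i] == 1 ? rtnorm_above(cm, csd, 0.0)
                              : rtnorm_below(cm, csd, 0.0);
      }

      // 2. subtrial coefficient blocks (conjugate MVN given Sigma)
      double det = sigma1 * sigma1 * (1.0 - rho * rho);
      double q11 = 1.0 / det;                       // inv Sigma entries
      double q12 = -rho * sigma1 / det;
      double q22 = sigma1 * sigma1 / det;
      for (int k = 0; k < K; k++) {
        arma::vec Sxy2(3, arma::fill::zeros);
        for (size_t ii = 0; ii < idx[k].size(); ii++) {
          int i = idx[k][ii];
          arma::vec x = {1.0, lx[i], tt[i]};
          Sxy2 += x * ystar[i];
        }
        arma::mat Pm(6, 6, arma::fill::zeros);
        Pm.submat(0, 0, 2, 2) = q11 * Sxx[k];
        Pm.submat(0, 3, 2, 5) = q12 * Sxx[k];
        Pm.submat(3, 0, 5, 2) = q12 * Sxx[k];
        Pm.submat(3, 3, 5, 5) = q22 * Sxx[k];
        arma::vec rhs(6);
        rhs.subvec(0, 2) = q11 * Sxy1[k] + q12 * Sxy2;
        rhs.subvec(3, 5) = q12 * Sxy1[k] + q22 * Sxy2;
        for (int j = 0; j < 6; j++) {
          double pm, pv;
          if (sharing) { pm = hmu[j]; pv = hsd[j] * hsd[j]; }
          else {
            pm = 0.0;
            double s0 = (j % 3 == 2) ? sd_treat_strat : sd_coef;
            pv = s0 * s0;
          }
          Pm(j, j) += 1.0 / pv;
          rhs[j] += pm / pv;
        }
        coef.row(k) = rmvnorm_prec(rhs, Pm).t();
      }

      if (sharing) {
        // 3. hierarchical means
        for (int j = 0; j < 6; j++) {
          double v = hsd[j] * hsd[j];
          double prec = 1.0 / (sd_coef * sd_coef) + K / v;
          double mean = arma::accu(coef.col(j)) / v / prec;
          hmu[j] = mean + R::norm_rand() / std::sqrt(prec);
        }
        // 4. hierarchical SDs, Exp(exp_rate) truncated below at trunc_lb
        for (int j = 0; j < 6; j++) {
          double ss = 0.0;
          for (int k = 0; k < K; k++) {
            double d = coef(k, j) - hmu[j];
            ss += d * d;
          }
          double cur = hsd[j];
          auto lf = [&](double s) {
            return -exp_rate * s - K * std::log(s) - ss / (2.0 * s * s);
          };
          hsd[j] = slice1(cur, lf, 0.5, trunc_lb, 50.0);
        }
      }

      // residual cross-products for (sigma1, rho)
      double S11 = 0.0, S12 = 0.0, S22 = 0.0;
      for (int i = 0; i < N; i++) {
        int k = sub[i];
        double r1 = y1[i] - (coef(k, 0) + coef(k, 1) * lx[i] + coef(k, 2) * tt[i]);
        double r2 = ystar[i] - (coef(k, 3) + coef(k, 4) * lx[i] + coef(k, 5) * tt[i]);
        S11 += r1 * r1; S12 += r1 * r2; S22 += r2 * r2;
      }

      // 5. sigma1 (slice on log scale; IG(shape, scale) prior on sigma1)
      {
        double r2c = 1.0 - rho * rho;
        auto lf = [&](double ls) {
          double s = std::exp(ls);
          return -(sig1_shape + 1.0) * ls - sig1_scale / s + ls -
                 N * ls -
                 (S11 / (s * s) - 2.0 * rho * S12 / s) / (2.0 * r2c);
        };
        sigma1 = std::exp(slice1(std::log(sigma1), lf, 0.3, -10.0, 10.0));
      }

      // 6. rho (slice; LKJ(eta) prior => (1-rho^2)^(eta-1))
      {
        auto lf = [&](double r) {
          double r2c = 1.0 - r * r;
          return (lkj_eta - 1.0) * std::log(r2c) -
                 0.5 * N * std::log(r2c) -
                 (S11 / (sigma1 * sigma1) - 2.0 * r * S12 / sigma1 + S22) /
                     (2.0 * r2c);
        };
        rho = slice1(rho, lf, 0.2, -1.0 + 1e-9, 1.0 - 1e-9);
      }

      if (it >= n_warmup) {
        int row = it - n_warmup, c = 0;
        for (int k = 0; k < K; k++)
          for (int j = 0; j < 6; j++) out(row, c++) = coef(k, j);
        if (sharing) {
          for (int j = 0; j < 6; j++) out(row, c++) = hmu[j];
          for (int j = 0; j < 6; j++) out(row, c++) = hsd[j];
        }
        out(row, c++) = sigma1;
        out(row, c++) = rho;
      }
    }
    chains[ch] = wrap(out);
  }
  return chains;
}

// ---- BIN ----------------------------------------------------------------

// [[Rcpp::export]]
List bin_gibbs_cpp(IntegerVector resp_, NumericVector lx_, NumericVector t_,
                   IntegerVector sub_, int K, bool sharing, int n_chains,
                   int n_warmup, int n_iter, double sd_coef,
                   double exp_rate, double trunc_lb)
{
  int N = resp_.size();
  arma::vec lx(lx_.begin(), N), tt(t_.begin(), N);
  arma::ivec resp(N), sub(N);
  for (int i = 0; i < N; i++) { resp[i] = resp_[i]; sub[i] = sub_[i] - 1; }
  std::vector<std::vector<int> > idx(K);
  for (int i = 0; i < N; i++) idx[sub[i]].push_back(i);

  int P = K * 3 + (sharing ? 6 : 0);
  List chains(n_chains);

  for (int ch = 0; ch < n_chains; ch++) {
    arma::mat coef(K, 3, arma::fill::zeros);
    for (int k = 0; k < K; k++)
      for (int j = 0; j < 3; j++) coef(k, j) = 0.2 * R::norm_rand();
    arma::vec hmu(3, arma::fill::zeros), hsd(3, arma::fill::ones);
    hsd *= 0.5 + trunc_lb;

    arma::mat out(n_iter, P);
    int total = n_warmup + n_iter;

    for (int it = 0; it < total; it++) {
      for (int k = 0; k < K; k++) {
        for (int j = 0; j < 3; j++) {
          double pm = sharing ? hmu[j] : 0.0;
          double ps = sharing ? hsd[j] : sd_coef;
          double cur = coef(k, j);
          auto lf = [&](double v) {
            double lp = -(v - pm) * (v - pm) / (2.0 * ps * ps);
            for (size_t ii = 0; ii < idx[k].size(); ii++) {
              int i = idx[k][ii];
              double xj = j == 0 ? 1.0 : (j == 1 ? lx[i] : tt[i]);
              double eta = coef(k, 0) + coef(k, 1) * lx[i] +
                           coef(k, 2) * tt[i] + (v - cur) * xj;
              lp += resp[i] * eta - R::log1pexp(eta);
            }
            return lp;
          };
          coef(k, j) = slice1(cur, lf, 1.0, -40.0, 40.0);
        }
      }
      if (sharing) {
        for (int j = 0; j < 3; j++) {
          double v = hsd[j] * hsd[j];
          double prec = 1.0 / (sd_coef * sd_coef) + K / v;
          double mean = arma::accu(coef.col(j)) / v / prec;
          hmu[j] = mean + R::norm_rand() / std::sqrt(prec);
        }
        for (int j = 0; j < 3; j++) {
          double ss = 0.0;
          for (int k = 0; k < K; k++) {
            double d = coef(k, j) - hmu[j];
            ss += d * d;
          }
          auto lf = [&](double s) {
            return -exp_rate * s - K * std::log(s) - ss / (2.0 * s * s);
          };
          hsd[j] = slice1(hsd[j], lf, 0.5, trunc_lb, 50.0);
        }
      }
      if (it >= n_warmup) {
        int row = it - n_warmup, c = 0;
        for (int k = 0; k < K; k++)
          for (int j = 0; j < 3; j++) out(row, c++) = coef(k, j);
        if (sharing) {
          for (int j = 0; j < 3; j++) out(row, c++) = hmu[j];
          for (int j = 0; j < 3; j++) out(row, c++) = hsd[j];
        }
      }
    }
    chains[ch] = wrap(out);
  }
  return chains;
}
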