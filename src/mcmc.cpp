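// Adaptive Metropolis-within-Gibbs sampler for the two-level hierarchical
// growth and mortality models.
//
// Structure per iteration:
//   - per-species 5-vector beta_j: random-walk Metropolis. During the first
//     half of burn-in the walk is componentwise with Robbins-Monro step
//     adaptation (target acceptance 0.44); an empirical covariance is then
//     accumulated and the second half uses a joint proposal shaped by it
//     (target 0.25). Proposals are frozen when sampling starts, so the
//     recorded chain is Markov.
//   - second-level gamma rows: exact conjugate multivariate-normal draws
//     (normal likelihood of beta around A gamma_k with sd sigma_k, normal
//     prior with sd gamma_sd).
//   - hyper-SDs sigma_k, the growth t scale sigma (uniform priors on a
//     bounded interval) and the normality nu (shifted-exponential prior)
//     move by log-scale random walks with the appropriate Jacobians.
//
// All randomness comes from R's RNG, so set.seed() in R makes chains
// reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log(1 - exp(a)) for a < 0
static inline double log1mexp_(double a) {
  if (a >= 0.0) return R_NegInf;
  if (a > -M_LN2) return std::log(-std::expm1(a));
  return std::log1p(-std::exp(a));
}

struct DemogData {
  const arma::mat& X;        // N x 5 covariates
  const arma::vec& y;        // growth: observed RGR; mortality: status (0/1)
  const arma::vec& interval; // mortality only
  bool growth;
};

// t log-kernel for a species block (terms depending on beta only)
static double growth_block_ll(const arma::vec& r, double sigma, double nu) {
  double s = 0.0, inv = 1.0 / (nu * sigma * sigma), c = -(nu + 1.0) / 2.0;
  for (arma::uword i = 0; i < r.n_elem; ++i)
    s += c * std::log1p(r[i] * r[i] * inv);
  return s;
}

// full t log-likelihood over all residuals (for sigma / nu moves)
static double growth_full_ll(const arma::vec& r, double sigma, double nu) {
  double cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0) -
               0.5 * std::log(nu * M_PI) - std::log(sigma);
  return r.n_elem * cst + growth_block_ll(r, sigma, nu);
}

// interval-censored Bernoulli log-likelihood for a block of trees
static double mort_block_ll(const arma::vec& eta, const arma::vec& status,
                            const arma::vec& interval) {
  double s = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double lsurv = -interval[i] * log1pexp_(eta[i]); // T * log(1 - p_annual)
    s += (status[i] > 0.5) ? log1mexp_(lsurv) : lsurv;
  }
  return s;
}

// [[Rcpp::export]]
arma::mat run_demog_chain(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& sp_start, const arma::ivec& sp_end,
                          const arma::mat& A, bool growth,
                          const arma::vec& interval,
                          List init, List prior,
                          int n_burnin, int n_save, int thin,
                          bool fixed_hyper) {
  const int S = A.n_rows;
  const int K = 5, M = 8;
  const double gamma_sd = as<double>(prior["gamma_sd"]);
  const double sk_lo = as<double>(prior["sigma_k_lo"]);
  const double sk_hi = as<double>(prior["sigma_k_hi"]);
  const double s_lo = as<double>(prior["sigma_lo"]);
  const double s_hi = as<double>(prior["sigma_hi"]);
  const double nu_mean = as<double>(prior["nu_mean"]); // mean of Exp on nu - 1

  arma::mat beta = as<arma::mat>(init["beta"]);     // S x 5
  arma::mat gamma = as<arma::mat>(init["gamma"]);   // 5 x 8
  arma::vec sk = as<arma::vec>(init["sigma_k"]);    // 5
  double sigma = growth ? as<double>(init["sigma"]) : 1.0;
  double nu = growth ? as<double>(init["nu"]) : 10.0;
  arma::vec prop_scale = as<arma::vec>(init["prop_scale"]); // 5

  // predictor / residual state
  arma::vec pred(X.n_rows);
  for (int j = 0; j < S; ++j) {
    pred.subvec(sp_start[j], sp_end[j] - 1) =
      X.rows(sp_start[j], sp_end[j] - 1) * beta.row(j).t();
  }
  arma::vec resid = growth ? arma::vec(y - pred) : arma::vec();

  // second-level means
  arma::mat mu = A * gamma.t(); // S x 5
  arma::mat AtA = A.t() * A;

  // adaptation state
  arma::mat ls_comp(S, K);
  for (int k = 0; k < K; ++k) ls_comp.col(k).fill(std::log(0.1 * prop_scale[k]));
  arma::vec ls_joint(S, arma::fill::value(std::log(2.38 / std::sqrt((double)K))));
  std::vector<arma::mat> L(S, arma::eye(K, K));
  std::vector<arma::vec> wmean(S, arma::vec(K, arma::fill::zeros));
  std::vector<arma::mat> wM2(S, arma::mat(K, K, arma::fill::zeros));
  int wcount = 0;
  arma::vec ls_sk(K, arma::fill::value(std::log(0.3)));
  double ls_sigma = std::log(0.1), ls_nu = std::log(0.3);
  // steps for the non-centered (interweaved) gamma-shift and sigma_k-rescale
  // moves that break the centered-parameterization funnel
  arma::mat ls_shift(K, M);
  for (int k = 0; k < K; ++k) ls_shift.row(k).fill(std::log(0.1 * prop_scale[k]));
  arma::vec ls_resc(K, arma::fill::value(std::log(0.3)));

  // per-tree species index (for vectorized shift moves)
  arma::ivec spv(X.n_rows);
  for (int j = 0; j < S; ++j)
    for (int i = sp_start[j]; i < sp_end[j]; ++i) spv[i] = j;
  // cached per-tree products X(i,k) * A(sp(i),m) for the shift moves, and
  // centred variants (X(i,k) - mean_k) * A(sp(i),m) for the collinear
  // shifts along the intercept trade-off direction
  arma::rowvec xbar = arma::mean(X, 0);
  std::vector<std::vector<arma::vec>> XA(K, std::vector<arma::vec>(M));
  std::vector<std::vector<arma::vec>> XAc(K, std::vector<arma::vec>(M));
  for (int k = 0; k < K; ++k)
    for (int mm = 0; mm < M; ++mm) {
      arma::vec v(X.n_rows), vc(X.n_rows);
      for (arma::uword i = 0; i < X.n_rows; ++i) {
        v[i] = X(i, k) * A(spv[i], mm);
        vc[i] = (X(i, k) - xbar[k]) * A(spv[i], mm);
      }
      XA[k][mm] = v; XAc[k][mm] = vc;
    }
  arma::mat ls_cshift(K, M);
  for (int k = 1; k < K; ++k) ls_cshift.row(k).fill(std::log(0.1 * prop_scale[k]));

  const int b_half = std::max(2, n_burnin / 2);
  const int b_quarter = std::max(1, n_burnin / 4);
  const int b_3q = std::max(b_half + 2, 3 * n_burnin / 4);
  const int n_iter = n_burnin + n_save * thin;

  const int P = S * K + K * M + K + (growth ? 2 : 0);
  arma::mat out(n_save, P);
  int save_row = 0;

  for (int t = 0; t < n_iter; ++t) {
    const bool adapting = t < n_burnin;
    const bool comp_phase = t < b_half;
    const double adapt_gain = std::min(0.25, 2.0 / std::sqrt((double)(t % b_half) + 1.0));

    // --- beta updates ---
    for (int j = 0; j < S; ++j) {
      const int a = sp_start[j], b = sp_end[j] - 1;
      const arma::mat Xj = X.rows(a, b);
      arma::vec bj = beta.row(j).t();
      if (comp_phase) {
        for (int k = 0; k < K; ++k) {
          double step = std::exp(ls_comp(j, k));
          arma::vec bp = bj;
          bp[k] += step * R::norm_rand();
          double cur_ll, new_ll;
          if (growth) {
            cur_ll = growth_block_ll(resid.subvec(a, b), sigma, nu);
            arma::vec rp = y.subvec(a, b) - Xj * bp;
            new_ll = growth_block_ll(rp, sigma, nu);
          } else {
            cur_ll = mort_block_ll(pred.subvec(a, b), y.subvec(a, b),
                                   interval.subvec(a, b));
            arma::vec ep = Xj * bp;
            new_ll = mort_block_ll(ep, y.subvec(a, b), interval.subvec(a, b));
          }
          double dprior = -0.5 * std::pow((bp[k] - mu(j, k)) / sk[k], 2) +
                          0.5 * std::pow((bj[k] - mu(j, k)) / sk[k], 2);
          bool acc = std::log(R::unif_rand()) < new_ll - cur_ll + dprior;
          if (acc) {
            bj = bp;
            arma::vec np = Xj * bj;
            pred.subvec(a, b) = np;
            if (growth) resid.subvec(a, b) = y.subvec(a, b) - np;
          }
          if (adapting)
            ls_comp(j, k) += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
      } else {
        double step = std::exp(ls_joint[j]);
        arma::vec z(K);
        for (int k = 0; k < K; ++k) z[k] = R::norm_rand();
        arma::vec bp = bj + step * (L[j] * z);
        double cur_ll, new_ll;
        if (growth) {
          cur_ll = growth_block_ll(resid.subvec(a, b), sigma, nu);
          arma::vec rp = y.subvec(a, b) - Xj * bp;
          new_ll = growth_block_ll(rp, sigma, nu);
        } else {
          cur_ll = mort_block_ll(pred.subvec(a, b), y.subvec(a, b),
                                 interval.subvec(a, b));
          arma::vec ep = Xj * bp;
          new_ll = mort_block_ll(ep, y.subvec(a, b), interval.subvec(a, b));
        }
        double dprior = 0.0;
        for (int k = 0; k < K; ++k) {
          dprior += -0.5 * std::pow((bp[k] - mu(j, k)) / sk[k], 2) +
                    0.5 * std::pow((bj[k] - mu(j, k)) / sk[k], 2);
        }
        bool acc = std::log(R::unif_rand()) < new_ll - cur_ll + dprior;
        if (acc) {
          bj = bp;
          arma::vec np = Xj * bj;
          pred.subvec(a, b) = np;
          if (growth) resid.subvec(a, b) = y.subvec(a, b) - np;
        }
        if (adapting) ls_joint[j] += adapt_gain * ((acc ? 1.0 : 0.0) - 0.25);
      }
      beta.row(j) = bj.t();
    }

    // accumulate moments for the joint proposal covariance
    if (t >= b_quarter && t < b_half) {
      ++wcount;
      for (int j = 0; j < S; ++j) {
        arma::vec bj = beta.row(j).t();
        arma::vec d = bj - wmean[j];
        wmean[j] += d / wcount;
        wM2[j] += d * (bj - wmean[j]).t();
      }
    }
    if ((t + 1 == b_half || t + 1 == b_3q) && wcount > K + 2) {
      for (int j = 0; j < S; ++j) {
        arma::mat C = wM2[j] / (wcount - 1);
        C = 0.5 * (C + C.t());
        // relative (per-dimension) ridge: coefficient scales differ by many
        // orders of magnitude, so an absolute or trace-based ridge would
        // wreck the proposal for the small-scale dimensions
        for (int d = 0; d < K; ++d)
          C(d, d) += std::max(1e-6 * C(d, d), 1e-30);
        arma::mat Lj;
        if (arma::chol(Lj, C, "lower")) {
          L[j] = Lj;
        } else {
          L[j] = arma::diagmat(arma::sqrt(arma::abs(C.diag()) + 1e-30));
        }
        wmean[j].zeros(); wM2[j].zeros();
      }
      if (t + 1 == b_half) wcount = 0;
    }
    if (t >= b_half && t < b_3q) { // refresh window for second covariance pass
      ++wcount;
      for (int j = 0; j < S; ++j) {
        arma::vec bj = beta.row(j).t();
        arma::vec d = bj - wmean[j];
        wmean[j] += d / wcount;
        wM2[j] += d * (bj - wmean[j]).t();
      }
    }

    if (!fixed_hyper) {
      // --- conjugate gamma rows ---
      for (int k = 0; k < K; ++k) {
        double tau = 1.0 / (sk[k] * sk[k]);
        arma::mat prec = AtA * tau;
        prec.diag() += 1.0 / (gamma_sd * gamma_sd);
        arma::vec rhs = A.t() * beta.col(k) * tau;
        arma::mat R = arma::chol(prec); // upper: R'R = prec
        arma::vec m = arma::solve(prec, rhs);
        arma::vec z(M);
        for (int mm = 0; mm < M; ++mm) z[mm] = R::norm_rand();
        arma::vec draw = m + arma::solve(arma::trimatu(R), z);
        gamma.row(k) = draw.t();
      }
      mu = A * gamma.t();

      // --- non-centered gamma shifts ---
      // Translate gamma(k, m) by delta and every beta(j, k) by A(j, m) *
      // delta simultaneously (the species-level residuals u = beta - mu are
      // held fixed), so the second-level location can move even when the
      // hyper-SD pins beta to mu. MH ratio: likelihood change + gamma prior
      // change; the beta prior is invariant under the joint translation.
      double cur_ll = growth ? growth_block_ll(resid, sigma, nu)
                             : mort_block_ll(pred, y, interval);
      for (int k = 0; k < K; ++k) {
        for (int mm = 0; mm < M; ++mm) {
          double delta = std::exp(ls_shift(k, mm)) * R::norm_rand();
          arma::vec dpred = delta * XA[k][mm];
          double new_ll = growth ? growth_block_ll(resid - dpred, sigma, nu)
                                 : mort_block_ll(pred + dpred, y, interval);
          double g0 = gamma(k, mm), g1 = g0 + delta;
          double dprior = -0.5 * (g1 * g1 - g0 * g0) / (gamma_sd * gamma_sd);
          bool acc = std::log(R::unif_rand()) < new_ll - cur_ll + dprior;
          if (acc) {
            gamma(k, mm) = g1;
            beta.col(k) += A.col(mm) * delta;
            mu.col(k) += A.col(mm) * delta;
            pred += dpred;
            if (growth) resid -= dpred;
            cur_ll = new_ll;
          }
          if (adapting) ls_shift(k, mm) += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }

      // --- collinear gamma shifts ---
      // Covariates enter uncentred, so gamma(k, m) for a slope row trades
      // off almost exactly against gamma(intercept, m) scaled by the
      // covariate mean. Move along that ridge: gamma(k, m) += delta with
      // gamma(intercept, m) -= xbar_k * delta (betas translated to match),
      // which changes the predictor only through X_k - xbar_k.
      for (int k = 1; k < K; ++k) {
        for (int mm = 0; mm < M; ++mm) {
          double delta = std::exp(ls_cshift(k, mm)) * R::norm_rand();
          arma::vec dpred = delta * XAc[k][mm];
          double new_ll = growth ? growth_block_ll(resid - dpred, sigma, nu)
                                 : mort_block_ll(pred + dpred, y, interval);
          double gk0 = gamma(k, mm), gk1 = gk0 + delta;
          double gi0 = gamma(0, mm), gi1 = gi0 - xbar[k] * delta;
          double dprior = -0.5 * (gk1 * gk1 - gk0 * gk0 + gi1 * gi1 - gi0 * gi0) /
                          (gamma_sd * gamma_sd);
          bool acc = std::log(R::unif_rand()) < new_ll - cur_ll + dprior;
          if (acc) {
            gamma(k, mm) = gk1; gamma(0, mm) = gi1;
            beta.col(k) += A.col(mm) * delta;
            beta.col(0) -= A.col(mm) * (xbar[k] * delta);
            mu.col(k) += A.col(mm) * delta;
            mu.col(0) -= A.col(mm) * (xbar[k] * delta);
            pred += dpred;
            if (growth) resid -= dpred;
            cur_ll = new_ll;
          }
          if (adapting) ls_cshift(k, mm) += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }

      // --- non-centered sigma_k rescales ---
      // Stretch the species deviations around mu by c and sigma_k with
      // them: beta' = mu + c (beta - mu), sigma_k' = c sigma_k. The beta
      // prior and the Jacobian cancel up to the +log c term.
      for (int k = 0; k < K; ++k) {
        double lc = std::exp(ls_resc[k]) * R::norm_rand();
        double c = std::exp(lc);
        double skp = sk[k] * c;
        bool acc = false;
        if (skp >= sk_lo && skp <= sk_hi) {
          arma::vec dbeta = (c - 1.0) * (beta.col(k) - mu.col(k));
          arma::vec dpred(X.n_rows);
          for (arma::uword i = 0; i < X.n_rows; ++i)
            dpred[i] = X(i, k) * dbeta[spv[i]];
          double cur_ll, new_ll;
          if (growth) {
            cur_ll = growth_block_ll(resid, sigma, nu);
            new_ll = growth_block_ll(resid - dpred, sigma, nu);
          } else {
            cur_ll = mort_block_ll(pred, y, interval);
            new_ll = mort_block_ll(pred + dpred, y, interval);
          }
          acc = std::log(R::unif_rand()) < new_ll - cur_ll + lc;
          if (acc) {
            sk[k] = skp;
            beta.col(k) += dbeta;
            pred += dpred;
            if (growth) resid -= dpred;
          }
        }
        if (adapting) ls_resc[k] += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
      }

      // --- sigma_k ---
      for (int k = 0; k < K; ++k) {
        double u = std::log(sk[k]);
        double up = u + std::exp(ls_sk[k]) * R::norm_rand();
        double skp = std::exp(up);
        bool acc = false;
        if (skp >= sk_lo && skp <= sk_hi) {
          arma::vec d = beta.col(k) - mu.col(k);
          double ss = arma::dot(d, d);
          double cur = -S * u - ss / (2.0 * sk[k] * sk[k]);
          double nw = -S * up - ss / (2.0 * skp * skp);
          acc = std::log(R::unif_rand()) < nw - cur + (up - u); // log-scale Jacobian
          if (acc) sk[k] = skp;
        }
        if (adapting) ls_sk[k] += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    if (growth) {
      // --- sigma (t scale) ---
      {
        double u = std::log(sigma);
        double up = u + std::exp(ls_sigma) * R::norm_rand();
        double sp = std::exp(up);
        bool acc = false;
        if (sp >= s_lo && sp <= s_hi) {
          double cur = growth_full_ll(resid, sigma, nu);
          double nw = growth_full_ll(resid, sp, nu);
          acc = std::log(R::unif_rand()) < nw - cur + (up - u);
          if (acc) sigma = sp;
        }
        if (adapting) ls_sigma += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
      // --- nu, sampled on log(nu - 1) ---
      {
        double u = std::log(nu - 1.0);
        double up = u + std::exp(ls_nu) * R::norm_rand();
        double nup = 1.0 + std::exp(up);
        double cur = growth_full_ll(resid, sigma, nu) + u - (nu - 1.0) / nu_mean;
        double nw = growth_full_ll(resid, sigma, nup) + up - (nup - 1.0) / nu_mean;
        bool acc = std::log(R::unif_rand()) < nw - cur;
        if (acc) nu = nup;
        if (adapting) ls_nu += adapt_gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // --- record ---
    if (t >= n_burnin && ((t - n_burnin) % thin == 0) && save_row < n_save) {
      int c = 0;
      for (int j = 0; j < S; ++j)
        for (int k = 0; k < K; ++k) out(save_row, c++) = beta(j, k);
      for (int k = 0; k < K; ++k)
        for (int mm = 0; mm < M; ++mm) out(save_row, c++) = gamma(k, mm);
      for (int k = 0; k < K; ++k) out(save_row, c++) = sk[k];
      if (growth) { out(save_row, c++) = sigma; out(save_row, c++) = nu; }
      ++save_row;
    }
  }
  return out;
}
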