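#include <Rcpp.h>
#include "orl.h"
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs samplers for the hierarchical models.
//
// All three models share the same group-level skeleton: per behavioral
// parameter, session-linked person-level values follow a bivariate normal
// with its own means, SDs and a 2x2 correlation matrix R (LKJ(1) prior,
// i.e. uniform on the off-diagonal r). Person-level values enter the
// likelihood through a non-centered parameterization,
//   raw_1 = mu_1 + sigma_1 * z_1
//   raw_2 = mu_2 + sigma_2 * (r * z_1 + sqrt(1 - r^2) * z_2)
// with z ~ N(0,1) i.i.d. Scalar coordinates are updated by adaptive
// random-walk Metropolis (Robbins-Monro step-size tuning toward 0.44
// acceptance during warmup). Because informative per-subject data makes
// the non-centered group parameters mix slowly, each group-level update is
// interleaved with an ancillarity-sufficiency interweaving (ASIS) move that
// re-expresses the same update in the centered system: the proposal shifts
// or rescales (mu, sigma, r) while shearing the latent z so that every
// person-level raw value -- and therefore the likelihood -- is unchanged;
// only prior and Jacobian terms enter the acceptance ratio. The pair of
// moves gives robust mixing in both data-poor and data-rich regimes.
//
// Missing sessions contribute no likelihood; their latents are refreshed
// directly from the conditional prior, which is exactly the structural
// imputation the joint model implies.

static inline double phi01(double x) { return ::Rf_pnorm5(x, 0.0, 1.0, 1, 0); }

// unnormalized log prior for a group SD
// type 0: half-normal(scale); 1: half-Cauchy(scale); 2: uniform(0, scale)
static inline double lp_sigma(double s, int type, double scale) {
  if (s <= 0.0) return R_NegInf;
  if (type == 0) return -0.5 * (s / scale) * (s / scale);
  if (type == 1) return -std::log1p((s / scale) * (s / scale));
  return (s < scale) ? 0.0 : R_NegInf;
}

static inline bool mh_accept(double la) {
  if (!R_finite(la)) return false;
  return la >= 0.0 || unif_rand() < std::exp(la);
}

static inline double acc_prob(double la) {
  if (!R_finite(la)) return 0.0;
  return la >= 0.0 ? 1.0 : std::exp(la);
}

static inline void adapt_ls(double &ls, double a, double gamma,
                            double target = 0.44) {
  ls += gamma * (a - target);
  if (ls < -8.0) ls = -8.0;
  if (ls > 3.0) ls = 3.0;
}

// ---------------------------------------------------------------------------
// Model 4: joint generative ORL across two sessions
// ---------------------------------------------------------------------------

static const int P = 5;  // A_rew, A_pun, K_prime, beta_f, beta_p

// Running moments of a subject's 5-dim latent block, used for joint
// adaptive-Metropolis proposals along the posterior's principal axes
// (single-coordinate moves traverse e.g. the K'/beta_p ridge very slowly).
struct AmStats {
  double mean[P];
  double cov[P * P];
  long n;
  AmStats() : n(0) {
    for (int a = 0; a < P; ++a) mean[a] = 0.0;
    for (int a = 0; a < P * P; ++a) cov[a] = 0.0;
  }
  void update(const double *x) {
    ++n;
    double dx[P];
    const double w = 1.0 / n;
    for (int a = 0; a < P; ++a) {
      dx[a] = x[a] - mean[a];
      mean[a] += w * dx[a];
    }
    for (int a = 0; a < P; ++a)
      for (int b = 0; b < P; ++b) cov[a * P + b] += dx[a] * (x[b] - mean[b]);
  }
  // Cholesky of cov/(n-1) + 1e-6 I; false until enough samples accrue
  bool chol(double *L) const {
    if (n < 50) return false;
    double S[P * P];
    for (int a = 0; a < P * P; ++a) S[a] = cov[a] / (n - 1);
    for (int a = 0; a < P; ++a) S[a * P + a] += 1e-6;
    for (int a = 0; a < P; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = S[a * P + b];
        for (int k = 0; k < b; ++k) s -= L[a * P + k] * L[b * P + k];
        if (a == b) {
          if (s <= 0) return false;
          L[a * P + a] = std::sqrt(s);
        } else {
          L[a * P + b] = s / L[b * P + b];
        }
      }
      for (int b = a + 1; b < P; ++b) L[a * P + b] = 0.0;
    }
    return true;
  }
  void propose(double eps, double *step) const {
    double L[P * P];
    double nrm[P];
    for (int a = 0; a < P; ++a) nrm[a] = norm_rand();
    if (chol(L)) {
      for (int a = 0; a < P; ++a) {
        double s = 0.0;
        for (int b = 0; b <= a; ++b) s += L[a * P + b] * nrm[b];
        step[a] = eps * s;
      }
    } else {
      for (int a = 0; a < P; ++a) step[a] = eps * nrm[a];
    }
  }
};

static inline double orl_ll_raw5(const std::vector<int> &deck,
                                 const std::vector<double> &x,
                                 const double *raw, double kmax) {
  const double a_rew = phi01(raw[0]);
  const double a_pun = phi01(raw[1]);
  const double kp = kmax * phi01(raw[2]);
  const double K = std::pow(3.0, kp) - 1.0;
  return orl_loglik_raw(deck.data(), x.data(), (int)deck.size(),
                        a_rew, a_pun, K, raw[3], raw[4]);
}

// [[Rcpp::export]]
List fit_m4_chain_cpp(List deck1_, List x1_, List deck2_, List x2_,
                      LogicalVector has2_, double kmax,
                      int n_keep, int warmup, int thin,
                      double mu_sd, NumericVector sg_scale,
                      IntegerVector sg_type) {
  const int n = deck1_.size();
  std::vector<std::vector<int> > deck1(n), deck2(n);
  std::vector<std::vector<double> > x1(n), x2(n);
  std::vector<bool> has2(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector d1 = deck1_[i];
    NumericVector v1 = x1_[i];
    deck1[i].assign(d1.begin(), d1.end());
    x1[i].assign(v1.begin(), v1.end());
    has2[i] = has2_[i];
    if (has2[i]) {
      IntegerVector d2 = deck2_[i];
      NumericVector v2 = x2_[i];
      deck2[i].assign(d2.begin(), d2.end());
      x2[i].assign(v2.begin(), v2.end());
    }
  }

  // state
  std::vector<double> mu0(P), mu1(P), sg0(P), sg1(P), eta(P);
  std::vector<double> z1(n * P), z2(n * P);
  std::vector<double> raw1(n * P), raw2(n * P), uu(n * P);
  std::vector<double> ll1(n), ll2(n, 0.0);

  // overdispersed chain inits (uses R's RNG; set.seed upstream)
  for (int p = 0; p < P; ++p) {
    mu0[p] = 0.3 * norm_rand();
    mu1[p] = 0.3 * norm_rand();
    double s0 = (sg_type[p] == 0) ? 0.7 * sg_scale[p] : 0.5;
    sg0[p] = s0 * std::exp(0.3 * norm_rand());
    sg1[p] = s0 * std::exp(0.3 * norm_rand());
    eta[p] = 0.8 * norm_rand();
  }
  for (int k = 0; k < n * P; ++k) {
    z1[k] = 0.3 * norm_rand();
    z2[k] = 0.3 * norm_rand();
  }

  auto refresh_raw = [&](int i) {
    for (int p = 0; p < P; ++p) {
      const int k = i * P + p;
      const double r = std::tanh(eta[p]), w = std::sqrt(1.0 - r * r);
      raw1[k] = mu0[p] + sg0[p] * z1[k];
      uu[k] = r * z1[k] + w * z2[k];
      raw2[k] = mu1[p] + sg1[p] * uu[k];
    }
  };
  for (int i = 0; i < n; ++i) {
    refresh_raw(i);
    ll1[i] = orl_ll_raw5(deck1[i], x1[i], &raw1[i * P], kmax);
    if (has2[i]) ll2[i] = orl_ll_raw5(deck2[i], x2[i], &raw2[i * P], kmax);
  }

  // log step sizes
  std::vector<double> ls_z1(n * P, std::log(0.4)), ls_z2(n * P, std::log(0.4));
  std::vector<double> ls_mu0(P, std::log(0.15)), ls_mu1(P, std::log(0.15));
  std::vector<double> ls_sg0(P, std::log(0.3)), ls_sg1(P, std::log(0.3));
  std::vector<double> ls_eta(P, std::log(0.4));
  std::vector<double> ls_amu0(P, std::log(0.15)), ls_amu1(P, std::log(0.15));
  std::vector<double> ls_asg0(P, std::log(0.3)), ls_asg1(P, std::log(0.3));
  std::vector<double> ls_aeta(P, std::log(0.4));
  std::vector<AmStats> am1(n), am2(n);
  std::vector<double> ls_j1(n, std::log(0.5)), ls_j2(n, std::log(0.5));

  const int n_cols = 4 * P + P + 2 * P * n;
  NumericMatrix draws(n_keep, n_cols);

  std::vector<double> tmp_raw(P), tmp_ll(n), tmp_rawcol(n);
  const int total = warmup + n_keep * thin;
  int kept = 0;

  for (int sweep = 1; sweep <= total; ++sweep) {
    const bool adapting = sweep <= warmup;
    const double gamma = adapting ? 1.0 / std::pow((double)sweep, 0.6) : 0.0;

    // ---- person-level latents ----
    for (int i = 0; i < n; ++i) {
      for (int p = 0; p < P; ++p) {
        const int k = i * P + p;
        const double r = std::tanh(eta[p]), w = std::sqrt(1.0 - r * r);
        // z1
        {
          const double zc = z1[k];
          const double zp = zc + std::exp(ls_z1[k]) * norm_rand();
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw1[i * P + q];
          tmp_raw[p] = mu0[p] + sg0[p] * zp;
          const double l1 = orl_ll_raw5(deck1[i], x1[i], tmp_raw.data(), kmax);
          double l2 = 0.0, raw2p = raw2[k], up = uu[k];
          if (has2[i]) {
            up = r * zp + w * z2[k];
            raw2p = mu1[p] + sg1[p] * up;
            for (int q = 0; q < P; ++q) tmp_raw[q] = raw2[i * P + q];
            tmp_raw[p] = raw2p;
            l2 = orl_ll_raw5(deck2[i], x2[i], tmp_raw.data(), kmax);
          } else {
            up = r * zp + w * z2[k];
            raw2p = mu1[p] + sg1[p] * up;
          }
          const double la = (l1 + l2) - (ll1[i] + ll2[i]) +
                            0.5 * (zc * zc - zp * zp);
          if (adapting) adapt_ls(ls_z1[k], acc_prob(la), gamma);
          if (mh_accept(la)) {
            z1[k] = zp;
            raw1[k] = mu0[p] + sg0[p] * zp;
            uu[k] = up;
            raw2[k] = raw2p;
            ll1[i] = l1;
            if (has2[i]) ll2[i] = l2;
          }
        }
        // z2
        if (!has2[i]) {
          z2[k] = norm_rand();
          uu[k] = r * z1[k] + w * z2[k];
          raw2[k] = mu1[p] + sg1[p] * uu[k];
        } else {
          const double zc = z2[k];
          const double zp = zc + std::exp(ls_z2[k]) * norm_rand();
          const double up = r * z1[k] + w * zp;
          const double raw2p = mu1[p] + sg1[p] * up;
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw2[i * P + q];
          tmp_raw[p] = raw2p;
          const double l2 = orl_ll_raw5(deck2[i], x2[i], tmp_raw.data(), kmax);
          const double la = l2 - ll2[i] + 0.5 * (zc * zc - zp * zp);
          if (adapting) adapt_ls(ls_z2[k], acc_prob(la), gamma);
          if (mh_accept(la)) {
            z2[k] = zp;
            uu[k] = up;
            raw2[k] = raw2p;
            ll2[i] = l2;
          }
        }
      }
    }

    // ---- joint latent updates along adapted covariance axes ----
    for (int i = 0; i < n; ++i) {
      double step[P], z1p[P], z2p[P], r1p[P], r2p[P], up[P];
      // session-1 block (moves raw1 and raw2 through the correlation)
      {
        am1[i].propose(std::exp(ls_j1[i]), step);
        double dpr = 0.0;
        for (int p = 0; p < P; ++p) {
          const int k = i * P + p;
          const double r = std::tanh(eta[p]), w = std::sqrt(1.0 - r * r);
          z1p[p] = z1[k] + step[p];
          r1p[p] = mu0[p] + sg0[p] * z1p[p];
          up[p] = r * z1p[p] + w * z2[k];
          r2p[p] = mu1[p] + sg1[p] * up[p];
          dpr += 0.5 * (z1[k] * z1[k] - z1p[p] * z1p[p]);
        }
        const double l1 = orl_ll_raw5(deck1[i], x1[i], r1p, kmax);
        const double l2 = has2[i] ? orl_ll_raw5(deck2[i], x2[i], r2p, kmax)
                                  : 0.0;
        const double la = (l1 + l2) - (ll1[i] + ll2[i]) + dpr;
        if (adapting) adapt_ls(ls_j1[i], acc_prob(la), gamma, 0.28);
        if (mh_accept(la)) {
          for (int p = 0; p < P; ++p) {
            const int k = i * P + p;
            z1[k] = z1p[p];
            raw1[k] = r1p[p];
            uu[k] = up[p];
            raw2[k] = r2p[p];
          }
          ll1[i] = l1;
          if (has2[i]) ll2[i] = l2;
        }
      }
      // session-2 block (only when session 2 carries data)
      if (has2[i]) {
        am2[i].propose(std::exp(ls_j2[i]), step);
        double dpr = 0.0;
        for (int p = 0; p < P; ++p) {
          const int k = i * P + p;
          const double r = std::tanh(eta[p]), w = std::sqrt(1.0 - r * r);
          z2p[p] = z2[k] + step[p];
          up[p] = r * z1[k] + w * z2p[p];
          r2p[p] = mu1[p] + sg1[p] * up[p];
          dpr += 0.5 * (z2[k] * z2[k] - z2p[p] * z2p[p]);
        }
        const double l2 = orl_ll_raw5(deck2[i], x2[i], r2p, kmax);
        const double la = l2 - ll2[i] + dpr;
        if (adapting) adapt_ls(ls_j2[i], acc_prob(la), gamma, 0.28);
        if (mh_accept(la)) {
          for (int p = 0; p < P; ++p) {
            const int k = i * P + p;
            z2[k] = z2p[p];
            uu[k] = up[p];
            raw2[k] = r2p[p];
          }
          ll2[i] = l2;
        }
      }
      if (adapting) {
        double cur[P];
        for (int p = 0; p < P; ++p) cur[p] = z1[i * P + p];
        am1[i].update(cur);
        for (int p = 0; p < P; ++p) cur[p] = z2[i * P + p];
        am2[i].update(cur);
      }
    }

    // ---- group-level, per parameter ----
    for (int p = 0; p < P; ++p) {
      const double r = std::tanh(eta[p]), w = std::sqrt(1.0 - r * r);

      // mu session 1: non-centered MH
      {
        const double mc = mu0[p];
        const double mp = mc + std::exp(ls_mu0[p]) * norm_rand();
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw1[i * P + q];
          tmp_raw[p] = mp + sg0[p] * z1[i * P + p];
          tmp_rawcol[i] = tmp_raw[p];
          tmp_ll[i] = orl_ll_raw5(deck1[i], x1[i], tmp_raw.data(), kmax);
          dll += tmp_ll[i] - ll1[i];
        }
        const double la = dll + 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        if (adapting) adapt_ls(ls_mu0[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu0[p] = mp;
          for (int i = 0; i < n; ++i) {
            raw1[i * P + p] = tmp_rawcol[i];
            ll1[i] = tmp_ll[i];
          }
        }
      }
      // mu session 1: ASIS shift (likelihood-free, raw held fixed)
      if (w > 1e-8) {
        const double delta = std::exp(ls_amu0[p]) * norm_rand();
        const double mc = mu0[p], mp = mc + delta;
        double la = 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        const double dz1 = -delta / sg0[p];
        const double dz2 = (r * delta / sg0[p]) / w;
        for (int i = 0; i < n; ++i) {
          const int k = i * P + p;
          const double a = z1[k], ap = a + dz1;
          const double b = z2[k], bp = b + dz2;
          la += 0.5 * (a * a - ap * ap) + 0.5 * (b * b - bp * bp);
        }
        if (adapting) adapt_ls(ls_amu0[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu0[p] = mp;
          for (int i = 0; i < n; ++i) {
            const int k = i * P + p;
            z1[k] += dz1;
            z2[k] += dz2;
          }
        }
      }
      // mu session 2: non-centered MH (only subjects with session 2 carry data)
      {
        const double mc = mu1[p];
        const double mp = mc + std::exp(ls_mu1[p]) * norm_rand();
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          tmp_rawcol[i] = mp + sg1[p] * uu[i * P + p];
          if (has2[i]) {
            for (int q = 0; q < P; ++q) tmp_raw[q] = raw2[i * P + q];
            tmp_raw[p] = tmp_rawcol[i];
            tmp_ll[i] = orl_ll_raw5(deck2[i], x2[i], tmp_raw.data(), kmax);
            dll += tmp_ll[i] - ll2[i];
          }
        }
        const double la = dll + 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        if (adapting) adapt_ls(ls_mu1[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu1[p] = mp;
          for (int i = 0; i < n; ++i) {
            raw2[i * P + p] = tmp_rawcol[i];
            if (has2[i]) ll2[i] = tmp_ll[i];
          }
        }
      }
      // mu session 2: ASIS shift
      if (w > 1e-8) {
        const double delta = std::exp(ls_amu1[p]) * norm_rand();
        const double mc = mu1[p], mp = mc + delta;
        double la = 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        const double dz2 = -delta / (sg1[p] * w);
        for (int i = 0; i < n; ++i) {
          const int k = i * P + p;
          const double b = z2[k], bp = b + dz2;
          la += 0.5 * (b * b - bp * bp);
        }
        if (adapting) adapt_ls(ls_amu1[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu1[p] = mp;
          for (int i = 0; i < n; ++i) {
            const int k = i * P + p;
            z2[k] += dz2;
            uu[k] = r * z1[k] + w * z2[k];
          }
        }
      }
      // sigma session 1: non-centered MH on log scale
      {
        const double sc = sg0[p];
        const double t = std::exp(ls_sg0[p]) * norm_rand();
        const double sp = sc * std::exp(t);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw1[i * P + q];
          tmp_raw[p] = mu0[p] + sp * z1[i * P + p];
          tmp_rawcol[i] = tmp_raw[p];
          tmp_ll[i] = orl_ll_raw5(deck1[i], x1[i], tmp_raw.data(), kmax);
          dll += tmp_ll[i] - ll1[i];
        }
        const double la = dll + lp_sigma(sp, sg_type[p], sg_scale[p]) -
                          lp_sigma(sc, sg_type[p], sg_scale[p]) + t;
        if (adapting) adapt_ls(ls_sg0[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg0[p] = sp;
          for (int i = 0; i < n; ++i) {
            raw1[i * P + p] = tmp_rawcol[i];
            ll1[i] = tmp_ll[i];
          }
        }
      }
      // sigma session 1: ASIS rescale
      if (w > 1e-8) {
        const double t = std::exp(ls_asg0[p]) * norm_rand();
        const double c = std::exp(t);
        const double sc = sg0[p], sp = sc * c;
        double la = lp_sigma(sp, sg_type[p], sg_scale[p]) -
                    lp_sigma(sc, sg_type[p], sg_scale[p]) + t - n * t;
        std::vector<double> z1p(n), z2p(n);
        for (int i = 0; i < n; ++i) {
          const int k = i * P + p;
          z1p[i] = z1[k] / c;
          z2p[i] = z2[k] + r * (z1[k] - z1p[i]) / w;
          la += 0.5 * (z1[k] * z1[k] - z1p[i] * z1p[i]) +
                0.5 * (z2[k] * z2[k] - z2p[i] * z2p[i]);
        }
        if (adapting) adapt_ls(ls_asg0[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg0[p] = sp;
          for (int i = 0; i < n; ++i) {
            const int k = i * P + p;
            z1[k] = z1p[i];
            z2[k] = z2p[i];
          }
        }
      }
      // sigma session 2: non-centered MH on log scale
      {
        const double sc = sg1[p];
        const double t = std::exp(ls_sg1[p]) * norm_rand();
        const double sp = sc * std::exp(t);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          tmp_rawcol[i] = mu1[p] + sp * uu[i * P + p];
          if (has2[i]) {
            for (int q = 0; q < P; ++q) tmp_raw[q] = raw2[i * P + q];
            tmp_raw[p] = tmp_rawcol[i];
            tmp_ll[i] = orl_ll_raw5(deck2[i], x2[i], tmp_raw.data(), kmax);
            dll += tmp_ll[i] - ll2[i];
          }
        }
        const double la = dll + lp_sigma(sp, sg_type[p], sg_scale[p]) -
                          lp_sigma(sc, sg_type[p], sg_scale[p]) + t;
        if (adapting) adapt_ls(ls_sg1[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg1[p] = sp;
          for (int i = 0; i < n; ++i) {
            raw2[i * P + p] = tmp_rawcol[i];
            if (has2[i]) ll2[i] = tmp_ll[i];
          }
        }
      }
      // sigma session 2: ASIS rescale
      if (w > 1e-8) {
        const double t = std::exp(ls_asg1[p]) * norm_rand();
        const double c = std::exp(t);
        const double sc = sg1[p], sp = sc * c;
        double la = lp_sigma(sp, sg_type[p], sg_scale[p]) -
                    lp_sigma(sc, sg_type[p], sg_scale[p]) + t - n * t;
        std::vector<double> z2p(n);
        for (int i = 0; i < n; ++i) {
          const int k = i * P + p;
          const double up = uu[k] / c;
          z2p[i] = (up - r * z1[k]) / w;
          la += 0.5 * (z2[k] * z2[k] - z2p[i] * z2p[i]);
        }
        if (adapting) adapt_ls(ls_asg1[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg1[p] = sp;
          for (int i = 0; i < n; ++i) {
            const int k = i * P + p;
            z2[k] = z2p[i];
            uu[k] /= c;
          }
        }
      }
      // correlation: non-centered MH on atanh scale
      {
        const double ec = eta[p];
        const double ep = ec + std::exp(ls_eta[p]) * norm_rand();
        const double rp = std::tanh(ep), wp = std::sqrt(1.0 - rp * rp);
        double dll = 0.0;
        std::vector<double> up(n), r2p(n);
        for (int i = 0; i < n; ++i) {
          const int k = i * P + p;
          up[i] = rp * z1[k] + wp * z2[k];
          r2p[i] = mu1[p] + sg1[p] * up[i];
          if (has2[i]) {
            for (int q = 0; q < P; ++q) tmp_raw[q] = raw2[i * P + q];
            tmp_raw[p] = r2p[i];
            tmp_ll[i] = orl_ll_raw5(deck2[i], x2[i], tmp_raw.data(), kmax);
            dll += tmp_ll[i] - ll2[i];
          }
        }
        const double la = dll + std::log1p(-rp * rp) - std::log1p(-r * r);
        if (adapting) adapt_ls(ls_eta[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          eta[p] = ep;
          for (int i = 0; i < n; ++i) {
            const int k = i * P + p;
            uu[k] = up[i];
            raw2[k] = r2p[i];
            if (has2[i]) ll2[i] = tmp_ll[i];
          }
        }
      }
      // correlation: ASIS move (u, hence raw2, held fixed)
      {
        const double rc = std::tanh(eta[p]), wc = std::sqrt(1.0 - rc * rc);
        if (wc > 1e-8) {
          const double ep = eta[p] + std::exp(ls_aeta[p]) * norm_rand();
          const double rp = std::tanh(ep), wp = std::sqrt(1.0 - rp * rp);
          if (wp > 1e-8) {
            double la = std::log1p(-rp * rp) - std::log1p(-rc * rc) +
                        n * (std::log(wc) - std::log(wp));
            std::vector<double> z2p(n);
            for (int i = 0; i < n; ++i) {
              const int k = i * P + p;
              z2p[i] = (uu[k] - rp * z1[k]) / wp;
              la += 0.5 * (z2[k] * z2[k] - z2p[i] * z2p[i]);
            }
            if (adapting) adapt_ls(ls_aeta[p], acc_prob(la), gamma);
            if (mh_accept(la)) {
              eta[p] = ep;
              for (int i = 0; i < n; ++i) z2[i * P + p] = z2p[i];
            }
          }
        }
      }
    }

    // ---- store ----
    if (sweep > warmup && (sweep - warmup) % thin == 0) {
      int c = 0;
      for (int p = 0; p < P; ++p) draws(kept, c++) = mu0[p];
      for (int p = 0; p < P; ++p) draws(kept, c++) = mu1[p];
      for (int p = 0; p < P; ++p) draws(kept, c++) = sg0[p];
      for (int p = 0; p < P; ++p) draws(kept, c++) = sg1[p];
      for (int p = 0; p < P; ++p) draws(kept, c++) = std::tanh(eta[p]);
      for (int i = 0; i < n; ++i) {
        for (int s = 0; s < 2; ++s) {
          const double *rw = (s == 0) ? &raw1[i * P] : &raw2[i * P];
          draws(kept, c++) = phi01(rw[0]);
          draws(kept, c++) = phi01(rw[1]);
          draws(kept, c++) = kmax * phi01(rw[2]);
          draws(kept, c++) = rw[3];
          draws(kept, c++) = rw[4];
        }
      }
      kept += 1;
    }
    if (sweep % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws);
}

// ---------------------------------------------------------------------------
// Model 3: per-session hierarchical ORL (independent normals)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fit_m3_chain_cpp(List deck_, List x_, double kmax,
                      int n_keep, int warmup, int thin,
                      double mu_sd, NumericVector sg_scale,
                      IntegerVector sg_type) {
  const int n = deck_.size();
  std::vector<std::vector<int> > deck(n);
  std::vector<std::vector<double> > x(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector d = deck_[i];
    NumericVector v = x_[i];
    deck[i].assign(d.begin(), d.end());
    x[i].assign(v.begin(), v.end());
  }

  std::vector<double> mu(P), sg(P), z(n * P), raw(n * P), ll(n);
  for (int p = 0; p < P; ++p) {
    mu[p] = 0.3 * norm_rand();
    double s0 = (sg_type[p] == 0) ? 0.7 * sg_scale[p] : 0.5;
    sg[p] = s0 * std::exp(0.3 * norm_rand());
  }
  for (int k = 0; k < n * P; ++k) z[k] = 0.3 * norm_rand();
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < P; ++p) raw[i * P + p] = mu[p] + sg[p] * z[i * P + p];
    ll[i] = orl_ll_raw5(deck[i], x[i], &raw[i * P], kmax);
  }

  std::vector<double> ls_z(n * P, std::log(0.4));
  std::vector<double> ls_mu(P, std::log(0.15)), ls_sg(P, std::log(0.3));
  std::vector<double> ls_amu(P, std::log(0.15)), ls_asg(P, std::log(0.3));
  std::vector<AmStats> am(n);
  std::vector<double> ls_j(n, std::log(0.5));

  const int n_cols = 2 * P + P * n;
  NumericMatrix draws(n_keep, n_cols);
  std::vector<double> tmp_raw(P), tmp_ll(n), tmp_rawcol(n);
  const int total = warmup + n_keep * thin;
  int kept = 0;

  for (int sweep = 1; sweep <= total; ++sweep) {
    const bool adapting = sweep <= warmup;
    const double gamma = adapting ? 1.0 / std::pow((double)sweep, 0.6) : 0.0;

    for (int i = 0; i < n; ++i) {
      for (int p = 0; p < P; ++p) {
        const int k = i * P + p;
        const double zc = z[k];
        const double zp = zc + std::exp(ls_z[k]) * norm_rand();
        for (int q = 0; q < P; ++q) tmp_raw[q] = raw[i * P + q];
        tmp_raw[p] = mu[p] + sg[p] * zp;
        const double l = orl_ll_raw5(deck[i], x[i], tmp_raw.data(), kmax);
        const double la = l - ll[i] + 0.5 * (zc * zc - zp * zp);
        if (adapting) adapt_ls(ls_z[k], acc_prob(la), gamma);
        if (mh_accept(la)) {
          z[k] = zp;
          raw[k] = tmp_raw[p];
          ll[i] = l;
        }
      }
    }

    // joint latent update along adapted covariance axes
    for (int i = 0; i < n; ++i) {
      double step[P], zp[P], rp[P];
      am[i].propose(std::exp(ls_j[i]), step);
      double dpr = 0.0;
      for (int p = 0; p < P; ++p) {
        const int k = i * P + p;
        zp[p] = z[k] + step[p];
        rp[p] = mu[p] + sg[p] * zp[p];
        dpr += 0.5 * (z[k] * z[k] - zp[p] * zp[p]);
      }
      const double l = orl_ll_raw5(deck[i], x[i], rp, kmax);
      const double la = l - ll[i] + dpr;
      if (adapting) adapt_ls(ls_j[i], acc_prob(la), gamma, 0.28);
      if (mh_accept(la)) {
        for (int p = 0; p < P; ++p) {
          const int k = i * P + p;
          z[k] = zp[p];
          raw[k] = rp[p];
        }
        ll[i] = l;
      }
      if (adapting) am[i].update(&z[i * P]);
    }

    for (int p = 0; p < P; ++p) {
      // mu: non-centered MH
      {
        const double mc = mu[p];
        const double mp = mc + std::exp(ls_mu[p]) * norm_rand();
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw[i * P + q];
          tmp_raw[p] = mp + sg[p] * z[i * P + p];
          tmp_rawcol[i] = tmp_raw[p];
          tmp_ll[i] = orl_ll_raw5(deck[i], x[i], tmp_raw.data(), kmax);
          dll += tmp_ll[i] - ll[i];
        }
        const double la = dll + 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        if (adapting) adapt_ls(ls_mu[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu[p] = mp;
          for (int i = 0; i < n; ++i) {
            raw[i * P + p] = tmp_rawcol[i];
            ll[i] = tmp_ll[i];
          }
        }
      }
      // mu: ASIS shift
      {
        const double delta = std::exp(ls_amu[p]) * norm_rand();
        const double mc = mu[p], mp = mc + delta;
        const double dz = -delta / sg[p];
        double la = 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
        for (int i = 0; i < n; ++i) {
          const double a = z[i * P + p], ap = a + dz;
          la += 0.5 * (a * a - ap * ap);
        }
        if (adapting) adapt_ls(ls_amu[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          mu[p] = mp;
          for (int i = 0; i < n; ++i) z[i * P + p] += dz;
        }
      }
      // sigma: non-centered MH on log scale
      {
        const double sc = sg[p];
        const double t = std::exp(ls_sg[p]) * norm_rand();
        const double sp = sc * std::exp(t);
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int q = 0; q < P; ++q) tmp_raw[q] = raw[i * P + q];
          tmp_raw[p] = mu[p] + sp * z[i * P + p];
          tmp_rawcol[i] = tmp_raw[p];
          tmp_ll[i] = orl_ll_raw5(deck[i], x[i], tmp_raw.data(), kmax);
          dll += tmp_ll[i] - ll[i];
        }
        const double la = dll + lp_sigma(sp, sg_type[p], sg_scale[p]) -
                          lp_sigma(sc, sg_type[p], sg_scale[p]) + t;
        if (adapting) adapt_ls(ls_sg[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg[p] = sp;
          for (int i = 0; i < n; ++i) {
            raw[i * P + p] = tmp_rawcol[i];
            ll[i] = tmp_ll[i];
          }
        }
      }
      // sigma: ASIS rescale
      {
        const double t = std::exp(ls_asg[p]) * norm_rand();
        const double c = std::exp(t);
        const double sc = sg[p], sp = sc * c;
        double la = lp_sigma(sp, sg_type[p], sg_scale[p]) -
                    lp_sigma(sc, sg_type[p], sg_scale[p]) + t - n * t;
        for (int i = 0; i < n; ++i) {
          const double a = z[i * P + p], ap = a / c;
          la += 0.5 * (a * a - ap * ap);
        }
        if (adapting) adapt_ls(ls_asg[p], acc_prob(la), gamma);
        if (mh_accept(la)) {
          sg[p] = sp;
          for (int i = 0; i < n; ++i) z[i * P + p] /= c;
        }
      }
    }

    if (sweep > warmup && (sweep - warmup) % thin == 0) {
      int c = 0;
      for (int p = 0; p < P; ++p) draws(kept, c++) = mu[p];
      for (int p = 0; p < P; ++p) draws(kept, c++) = sg[p];
      for (int i = 0; i < n; ++i) {
        const double *rw = &raw[i * P];
        draws(kept, c++) = phi01(rw[0]);
        draws(kept, c++) = phi01(rw[1]);
        draws(kept, c++) = kmax * phi01(rw[2]);
        draws(kept, c++) = rw[3];
        draws(kept, c++) = rw[4];
      }
      kept += 1;
    }
    if (sweep % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws);
}

// ---------------------------------------------------------------------------
// Model 2: joint binomial (probit) model of good-deck choice
// ---------------------------------------------------------------------------

static inline double binom_ll(int k, int T, double raw) {
  // k successes out of T with success probability Phi(raw)
  const double lp = ::Rf_pnorm5(raw, 0.0, 1.0, 1, 1);
  const double lq = ::Rf_pnorm5(raw, 0.0, 1.0, 0, 1);
  return k * lp + (T - k) * lq;
}

// [[Rcpp::export]]
List fit_m2_chain_cpp(IntegerVector k1, IntegerVector T1,
                      IntegerVector k2, IntegerVector T2,
                      LogicalVector has2, int n_keep, int warmup, int thin,
                      double mu_sd, double sg_upper) {
  const int n = k1.size();
  double mu0, mu1, sg0, sg1, eta;
  std::vector<double> z1(n), z2(n), raw1(n), raw2(n), uu(n), ll1(n),
      ll2(n, 0.0);

  mu0 = 0.3 * norm_rand();
  mu1 = 0.3 * norm_rand();
  sg0 = 0.3 * std::exp(0.3 * norm_rand());
  sg1 = 0.3 * std::exp(0.3 * norm_rand());
  eta = 0.8 * norm_rand();
  for (int i = 0; i < n; ++i) {
    z1[i] = 0.3 * norm_rand();
    z2[i] = 0.3 * norm_rand();
  }
  {
    const double r = std::tanh(eta), w = std::sqrt(1.0 - r * r);
    for (int i = 0; i < n; ++i) {
      raw1[i] = mu0 + sg0 * z1[i];
      uu[i] = r * z1[i] + w * z2[i];
      raw2[i] = mu1 + sg1 * uu[i];
      ll1[i] = binom_ll(k1[i], T1[i], raw1[i]);
      if (has2[i]) ll2[i] = binom_ll(k2[i], T2[i], raw2[i]);
    }
  }

  std::vector<double> ls_z1(n, std::log(0.4)), ls_z2(n, std::log(0.4));
  double ls_mu0 = std::log(0.1), ls_mu1 = std::log(0.1);
  double ls_sg0 = std::log(0.3), ls_sg1 = std::log(0.3);
  double ls_eta = std::log(0.4);
  double ls_amu0 = std::log(0.1), ls_amu1 = std::log(0.1);
  double ls_asg0 = std::log(0.3), ls_asg1 = std::log(0.3);
  double ls_aeta = std::log(0.4);

  NumericMatrix draws(n_keep, 5 + 2 * n);
  const int total = warmup + n_keep * thin;
  int kept = 0;
  std::vector<double> tmp_ll(n), tmp_rawcol(n);

  for (int sweep = 1; sweep <= total; ++sweep) {
    const bool adapting = sweep <= warmup;
    const double gamma = adapting ? 1.0 / std::pow((double)sweep, 0.6) : 0.0;
    const double r = std::tanh(eta), w = std::sqrt(1.0 - r * r);

    for (int i = 0; i < n; ++i) {
      // z1
      {
        const double zc = z1[i];
        const double zp = zc + std::exp(ls_z1[i]) * norm_rand();
        const double r1p = mu0 + sg0 * zp;
        const double up = r * zp + w * z2[i];
        const double r2p = mu1 + sg1 * up;
        const double l1 = binom_ll(k1[i], T1[i], r1p);
        const double l2 = has2[i] ? binom_ll(k2[i], T2[i], r2p) : 0.0;
        const double la = (l1 + l2) - (ll1[i] + ll2[i]) +
                          0.5 * (zc * zc - zp * zp);
        if (adapting) adapt_ls(ls_z1[i], acc_prob(la), gamma);
        if (mh_accept(la)) {
          z1[i] = zp;
          raw1[i] = r1p;
          uu[i] = up;
          raw2[i] = r2p;
          ll1[i] = l1;
          if (has2[i]) ll2[i] = l2;
        }
      }
      // z2
      if (!has2[i]) {
        z2[i] = norm_rand();
        uu[i] = r * z1[i] + w * z2[i];
        raw2[i] = mu1 + sg1 * uu[i];
      } else {
        const double zc = z2[i];
        const double zp = zc + std::exp(ls_z2[i]) * norm_rand();
        const double up = r * z1[i] + w * zp;
        const double r2p = mu1 + sg1 * up;
        const double l2 = binom_ll(k2[i], T2[i], r2p);
        const double la = l2 - ll2[i] + 0.5 * (zc * zc - zp * zp);
        if (adapting) adapt_ls(ls_z2[i], acc_prob(la), gamma);
        if (mh_accept(la)) {
          z2[i] = zp;
          uu[i] = up;
          raw2[i] = r2p;
          ll2[i] = l2;
        }
      }
    }

    // mu0 MH
    {
      const double mc = mu0, mp = mc + std::exp(ls_mu0) * norm_rand();
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        tmp_rawcol[i] = mp + sg0 * z1[i];
        tmp_ll[i] = binom_ll(k1[i], T1[i], tmp_rawcol[i]);
        dll += tmp_ll[i] - ll1[i];
      }
      const double la = dll + 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
      if (adapting) adapt_ls(ls_mu0, acc_prob(la), gamma);
      if (mh_accept(la)) {
        mu0 = mp;
        for (int i = 0; i < n; ++i) {
          raw1[i] = tmp_rawcol[i];
          ll1[i] = tmp_ll[i];
        }
      }
    }
    // mu0 ASIS
    if (w > 1e-8) {
      const double delta = std::exp(ls_amu0) * norm_rand();
      const double mc = mu0, mp = mc + delta;
      const double dz1 = -delta / sg0, dz2 = (r * delta / sg0) / w;
      double la = 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
      for (int i = 0; i < n; ++i)
        la += 0.5 * (z1[i] * z1[i] - (z1[i] + dz1) * (z1[i] + dz1)) +
              0.5 * (z2[i] * z2[i] - (z2[i] + dz2) * (z2[i] + dz2));
      if (adapting) adapt_ls(ls_amu0, acc_prob(la), gamma);
      if (mh_accept(la)) {
        mu0 = mp;
        for (int i = 0; i < n; ++i) {
          z1[i] += dz1;
          z2[i] += dz2;
        }
      }
    }
    // mu1 MH
    {
      const double mc = mu1, mp = mc + std::exp(ls_mu1) * norm_rand();
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        tmp_rawcol[i] = mp + sg1 * uu[i];
        if (has2[i]) {
          tmp_ll[i] = binom_ll(k2[i], T2[i], tmp_rawcol[i]);
          dll += tmp_ll[i] - ll2[i];
        }
      }
      const double la = dll + 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
      if (adapting) adapt_ls(ls_mu1, acc_prob(la), gamma);
      if (mh_accept(la)) {
        mu1 = mp;
        for (int i = 0; i < n; ++i) {
          raw2[i] = tmp_rawcol[i];
          if (has2[i]) ll2[i] = tmp_ll[i];
        }
      }
    }
    // mu1 ASIS
    if (w > 1e-8) {
      const double delta = std::exp(ls_amu1) * norm_rand();
      const double mc = mu1, mp = mc + delta;
      const double dz2 = -delta / (sg1 * w);
      double la = 0.5 * (mc * mc - mp * mp) / (mu_sd * mu_sd);
      for (int i = 0; i < n; ++i)
        la += 0.5 * (z2[i] * z2[i] - (z2[i] + dz2) * (z2[i] + dz2));
      if (adapting) adapt_ls(ls_amu1, acc_prob(la), gamma);
      if (mh_accept(la)) {
        mu1 = mp;
        for (int i = 0; i < n; ++i) {
          z2[i] += dz2;
          uu[i] = r * z1[i] + w * z2[i];
        }
      }
    }
    // sg0 MH
    {
      const double sc = sg0;
      const double t = std::exp(ls_sg0) * norm_rand();
      const double sp = sc * std::exp(t);
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        tmp_rawcol[i] = mu0 + sp * z1[i];
        tmp_ll[i] = binom_ll(k1[i], T1[i], tmp_rawcol[i]);
        dll += tmp_ll[i] - ll1[i];
      }
      const double la = dll + lp_sigma(sp, 2, sg_upper) -
                        lp_sigma(sc, 2, sg_upper) + t;
      if (adapting) adapt_ls(ls_sg0, acc_prob(la), gamma);
      if (mh_accept(la)) {
        sg0 = sp;
        for (int i = 0; i < n; ++i) {
          raw1[i] = tmp_rawcol[i];
          ll1[i] = tmp_ll[i];
        }
      }
    }
    // sg0 ASIS
    if (w > 1e-8) {
      const double t = std::exp(ls_asg0) * norm_rand();
      const double c = std::exp(t);
      const double sc = sg0, sp = sc * c;
      double la = lp_sigma(sp, 2, sg_upper) - lp_sigma(sc, 2, sg_upper) + t -
                  n * t;
      std::vector<double> z1p(n), z2p(n);
      for (int i = 0; i < n; ++i) {
        z1p[i] = z1[i] / c;
        z2p[i] = z2[i] + r * (z1[i] - z1p[i]) / w;
        la += 0.5 * (z1[i] * z1[i] - z1p[i] * z1p[i]) +
              0.5 * (z2[i] * z2[i] - z2p[i] * z2p[i]);
      }
      if (adapting) adapt_ls(ls_asg0, acc_prob(la), gamma);
      if (mh_accept(la)) {
        sg0 = sp;
        for (int i = 0; i < n; ++i) {
          z1[i] = z1p[i];
          z2[i] = z2p[i];
        }
      }
    }
    // sg1 MH
    {
      const double sc = sg1;
      const double t = std::exp(ls_sg1) * norm_rand();
      const double sp = sc * std::exp(t);
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        tmp_rawcol[i] = mu1 + sp * uu[i];
        if (has2[i]) {
          tmp_ll[i] = binom_ll(k2[i], T2[i], tmp_rawcol[i]);
          dll += tmp_ll[i] - ll2[i];
        }
      }
      const double la = dll + lp_sigma(sp, 2, sg_upper) -
                        lp_sigma(sc, 2, sg_upper) + t;
      if (adapting) adapt_ls(ls_sg1, acc_prob(la), gamma);
      if (mh_accept(la)) {
        sg1 = sp;
        for (int i = 0; i < n; ++i) {
          raw2[i] = tmp_rawcol[i];
          if (has2[i]) ll2[i] = tmp_ll[i];
        }
      }
    }
    // sg1 ASIS
    if (w > 1e-8) {
      const double t = std::exp(ls_asg1) * norm_rand();
      const double c = std::exp(t);
      const double sc = sg1, sp = sc * c;
      double la = lp_sigma(sp, 2, sg_upper) - lp_sigma(sc, 2, sg_upper) + t -
                  n * t;
      std::vector<double> z2p(n);
      for (int i = 0; i < n; ++i) {
        const double up = uu[i] / c;
        z2p[i] = (up - r * z1[i]) / w;
        la += 0.5 * (z2[i] * z2[i] - z2p[i] * z2p[i]);
      }
      if (adapting) adapt_ls(ls_asg1, acc_prob(la), gamma);
      if (mh_accept(la)) {
        sg1 = sp;
        for (int i = 0; i < n; ++i) {
          z2[i] = z2p[i];
          uu[i] /= c;
        }
      }
    }
    // eta MH
    {
      const double ec = eta;
      const double ep = ec + std::exp(ls_eta) * norm_rand();
      const double rp = std::tanh(ep), wp = std::sqrt(1.0 - rp * rp);
      double dll = 0.0;
      std::vector<double> up(n), r2p(n);
      for (int i = 0; i < n; ++i) {
        up[i] = rp * z1[i] + wp * z2[i];
        r2p[i] = mu1 + sg1 * up[i];
        if (has2[i]) {
          tmp_ll[i] = binom_ll(k2[i], T2[i], r2p[i]);
          dll += tmp_ll[i] - ll2[i];
        }
      }
      const double la = dll + std::log1p(-rp * rp) - std::log1p(-r * r);
      if (adapting) adapt_ls(ls_eta, acc_prob(la), gamma);
      if (mh_accept(la)) {
        eta = ep;
        for (int i = 0; i < n; ++i) {
          uu[i] = up[i];
          raw2[i] = r2p[i];
          if (has2[i]) ll2[i] = tmp_ll[i];
        }
      }
    }
    // eta ASIS
    {
      const double rc = std::tanh(eta), wc = std::sqrt(1.0 - rc * rc);
      if (wc > 1e-8) {
        const double ep = eta + std::exp(ls_aeta) * norm_rand();
        const double rp = std::tanh(ep), wp = std::sqrt(1.0 - rp * rp);
        if (wp > 1e-8) {
          double la = std::log1p(-rp * rp) - std::log1p(-rc * rc) +
                      n * (std::log(wc) - std::log(wp));
          std::vector<double> z2p(n);
          for (int i = 0; i < n; ++i) {
            z2p[i] = (uu[i] - rp * z1[i]) / wp;
            la += 0.5 * (z2[i] * z2[i] - z2p[i] * z2p[i]);
          }
          if (adapting) adapt_ls(ls_aeta, acc_prob(la), gamma);
          if (mh_accept(la)) {
            eta = ep;
            for (int i = 0; i < n; ++i) z2[i] = z2p[i];
          }
        }
      }
    }

    if (sweep > warmup && (sweep - warmup) % thin == 0) {
      int c = 0;
      draws(kept, c++) = mu0;
      draws(kept, c++) = mu1;
      draws(kept, c++) = sg0;
      draws(kept, c++) = sg1;
      draws(kept, c++) = std::tanh(eta);
      for (int i = 0; i < n; ++i) {
        draws(kept, c++) = phi01(raw1[i]);
        draws(kept, c++) = phi01(raw2[i]);
      }
      kept += 1;
    }
    if (sweep % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws);
}
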