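// Adaptive Metropolis-within-Gibbs sampler for the hierarchical logistic
// moult-progression model.
//
// Observation model: the integer score of observation i in cycle j is a
// rounded, clamped Normal read-out (sd sigma_obs) of the latent fraction
// logistic((t_i - t50_j)/scale_j), i.e. an interval-censored Normal pmf on
// 0..100, mixed with a small uniform contamination for gross errors.
// Cycle structure:  t50_j   = mu_t50 + a[anim_j] + b[year_j]
//                   log scale_j = mu_ls + c[anim_j] + d[year_j]
// with a, b, c, d zero-mean Normal with half-Normal hyper-priors on their
// sds, Normal priors on mu_t50 / mu_ls and a half-Normal prior on
// sigma_obs.  Scalar random-walk proposals, step sizes adapted during
// warmup toward 0.44 acceptance.  Uses R's RNG: seeding via set.seed() in
// the caller makes chains reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Model {
  const NumericVector &t, &y;
  const std::vector< std::vector<int> > &obs_of_cycle;
  double eps;   // fixed contamination weight (uniform over the 101 scores)
  double half;  // rounding half-width on the fraction scale (0.005)
  // Log-likelihood of all observations of cycle j.  An integer score k is
  // a rounded, clamped Normal read-out of the latent fraction:
  //   P(k) = Phi((k/100 + half - p)/sig) - Phi((k/100 - half - p)/sig),
  // with the lower tail absorbed into k = 0 and the upper into k = 100
  // (interval censoring), mixed with a uniform contamination for rare
  // gross scoring errors (0 <-> 100 flips).
  double cycle_ll(int j, double t50, double scale, double sig) const {
    double ll = 0.0;
    const std::vector<int> &idx = obs_of_cycle[j];
    for (size_t k = 0; k < idx.size(); ++k) {
      int i = idx[k];
      double p = logistic((t[i] - t50) / scale);
      double hi = (y[i] >= 1.0) ? 1.0 :
        R::pnorm((y[i] + half - p) / sig, 0.0, 1.0, 1, 0);
      double lo = (y[i] <= 0.0) ? 0.0 :
        R::pnorm((y[i] - half - p) / sig, 0.0, 1.0, 1, 0);
      double prob = hi - lo;
      if (prob < 0.0) prob = 0.0;
      double mixed = (1.0 - eps) * prob + eps / 101.0;
      ll += (mixed > 1e-300) ? std::log(mixed) : -1e300;
    }
    return ll;
  }
};

static inline double half_normal_lp(double sig, double s0) {
  // log density of sig ~ half-Normal(0, s0), sig > 0 (constant dropped)
  return -0.5 * (sig / s0) * (sig / s0);
}

// [[Rcpp::export]]
List mcmc_moult_chain(NumericVector t, NumericVector y, IntegerVector cyc,
                      IntegerVector anim, IntegerVector yr,
                      int n_anim, int n_year,
                      int iter, int warmup, NumericVector init, List prior) {
  const int n_obs = t.size();
  const int n_cyc = anim.size();
  const double m0 = prior["m0"], sd_mu_t50 = prior["sd_mu_t50"];
  const double nu0 = prior["nu0"], sd_mu_ls = prior["sd_mu_ls"];
  const double s_a = prior["s_a"], s_b = prior["s_b"];
  const double s_c = prior["s_c"], s_d = prior["s_d"];
  const double s_obs = prior["s_obs"];
  const double eps = prior.containsElementNamed("eps") ?
    Rcpp::as<double>(prior["eps"]) : 0.0;

  std::vector< std::vector<int> > obs_of_cycle(n_cyc);
  for (int i = 0; i < n_obs; ++i) obs_of_cycle[cyc[i]].push_back(i);
  std::vector< std::vector<int> > cyc_of_anim(n_anim), cyc_of_year(n_year);
  for (int j = 0; j < n_cyc; ++j) {
    cyc_of_anim[anim[j]].push_back(j);
    cyc_of_year[yr[j]].push_back(j);
  }
  Model mod{t, y, obs_of_cycle, eps, 0.005};

  // parameter vector: mu_t50, mu_ls, lsig_a, lsig_b, lsig_c, lsig_d,
  // lsig_obs, a[n_anim], b[n_year], c[n_anim], d[n_year]
  const int npar = 7 + 2 * n_anim + 2 * n_year;
  const int iA = 7, iB = iA + n_anim, iC = iB + n_year, iD = iC + n_anim;
  std::vector<double> th(init.begin(), init.end());
  if ((int)th.size() != npar) stop("bad init length");

  std::vector<double> t50(n_cyc), scl(n_cyc), llcyc(n_cyc);
  double sig = std::exp(th[6]);
  for (int j = 0; j < n_cyc; ++j) {
    t50[j] = th[0] + th[iA + anim[j]] + th[iB + yr[j]];
    scl[j] = std::exp(th[1] + th[iC + anim[j]] + th[iD + yr[j]]);
    llcyc[j] = mod.cycle_ll(j, t50[j], scl[j], sig);
  }

  std::vector<double> lstep(npar, std::log(0.1));
  lstep[0] = std::log(0.5);                  // mu_t50 in days
  for (int k = iA; k < iB; ++k) lstep[k] = std::log(0.5);
  for (int k = iB; k < iC; ++k) lstep[k] = std::log(0.3);
  std::vector<double> acc(npar, 0.0), tries(npar, 0.0);
  const double target = 0.44;

  int keep = iter - warmup;
  NumericMatrix draws(keep, npar);

  // generic accept/adapt helper (on log of acceptance ratio)
  auto adapt = [&](int k, double lr, int it) -> bool {
    double ap = lr >= 0 ? 1.0 : std::exp(lr);
    bool ok = std::log(R::runif(0.0, 1.0)) < lr;
    tries[k] += 1; if (ok) acc[k] += 1;
    if (it < warmup)
      lstep[k] += (ap - target) / std::pow(1.0 + it * 0.05, 0.7);
    return ok;
  };

  for (int it = 0; it < iter; ++it) {
    // --- mu_t50 (shifts every cycle's t50) ---
    {
      double prop = th[0] + R::rnorm(0.0, std::exp(lstep[0]));
      double lr = 0.0;
      std::vector<double> newll(n_cyc);
      for (int j = 0; j < n_cyc; ++j) {
        newll[j] = mod.cycle_ll(j, t50[j] + (prop - th[0]), scl[j], sig);
        lr += newll[j] - llcyc[j];
      }
      lr += (-0.5 * std::pow((prop - m0) / sd_mu_t50, 2)) -
            (-0.5 * std::pow((th[0] - m0) / sd_mu_t50, 2));
      if (adapt(0, lr, it)) {
        for (int j = 0; j < n_cyc; ++j) { t50[j] += prop - th[0]; llcyc[j] = newll[j]; }
        th[0] = prop;
      }
    }
    // --- mu_ls (scales every cycle) ---
    {
      double prop = th[1] + R::rnorm(0.0, std::exp(lstep[1]));
      double f = std::exp(prop - th[1]);
      double lr = 0.0;
      std::vector<double> newll(n_cyc);
      for (int j = 0; j < n_cyc; ++j) {
        newll[j] = mod.cycle_ll(j, t50[j], scl[j] * f, sig);
        lr += newll[j] - llcyc[j];
      }
      lr += (-0.5 * std::pow((prop - nu0) / sd_mu_ls, 2)) -
            (-0.5 * std::pow((th[1] - nu0) / sd_mu_ls, 2));
      if (adapt(1, lr, it)) {
        for (int j = 0; j < n_cyc; ++j) { scl[j] *= f; llcyc[j] = newll[j]; }
        th[1] = prop;
      }
    }
    // --- animal effects a[k] (t50) and c[k] (log scale) ---
    double sig_a = std::exp(th[2]), sig_b = std::exp(th[3]);
    double sig_c = std::exp(th[4]), sig_d = std::exp(th[5]);
    for (int k = 0; k < n_anim; ++k) {
      { // a[k]
        int pk = iA + k;
        double prop = th[pk] + R::rnorm(0.0, std::exp(lstep[pk]));
        double lr = 0.0;
        const std::vector<int> &cj = cyc_of_anim[k];
        std::vector<double> newll(cj.size());
        for (size_t m = 0; m < cj.size(); ++m) {
          int j = cj[m];
          newll[m] = mod.cycle_ll(j, t50[j] + (prop - th[pk]), scl[j], sig);
          lr += newll[m] - llcyc[j];
        }
        lr += -0.5 * (prop * prop - th[pk] * th[pk]) / (sig_a * sig_a);
        if (adapt(pk, lr, it)) {
          for (size_t m = 0; m < cj.size(); ++m) {
            int j = cj[m]; t50[j] += prop - th[pk]; llcyc[j] = newll[m];
          }
          th[pk] = prop;
        }
      }
      { // c[k]
        int pk = iC + k;
        double prop = th[pk] + R::rnorm(0.0, std::exp(lstep[pk]));
        double f = std::exp(prop - th[pk]);
        double lr = 0.0;
        const std::vector<int> &cj = cyc_of_anim[k];
        std::vector<double> newll(cj.size());
        for (size_t m = 0; m < cj.size(); ++m) {
          int j = cj[m];
          newll[m] = mod.cycle_ll(j, t50[j], scl[j] * f, sig);
          lr += newll[m] - llcyc[j];
        }
        lr += -0.5 * (prop * prop - th[pk] * th[pk]) / (sig_c * sig_c);
        if (adapt(pk, lr, it)) {
          for (size_t m = 0; m < cj.size(); ++m) {
            int j = cj[m]; scl[j] *= f; llcyc[j] = newll[m];
          }
          th[pk] = prop;
        }
      }
    }
    // --- year effects b[k] (t50) and d[k] (log scale) ---
    for (int k = 0; k < n_year; ++k) {
      { // b[k]
        int pk = iB + k;
        double prop = th[pk] + R::rnorm(0.0, std::exp(lstep[pk]));
        double lr = 0.0;
        const std::vector<int> &cj = cyc_of_year[k];
        std::vector<double> newll(cj.size());
        for (size_t m = 0; m < cj.size(); ++m) {
          int j = cj[m];
          newll[m] = mod.cycle_ll(j, t50[j] + (prop - th[pk]), scl[j], sig);
          lr += newll[m] - llcyc[j];
        }
        lr += -0.5 * (prop * prop - th[pk] * th[pk]) / (sig_b * sig_b);
        if (adapt(pk, lr, it)) {
          for (size_t m = 0; m < cj.size(); ++m) {
            int j = cj[m]; t50[j] += prop - th[pk]; llcyc[j] = newll[m];
          }
          th[pk] = prop;
        }
      }
      { // d[k]
        int pk = iD + k;
        double prop = th[pk] + R::rnorm(0.0, std::exp(lstep[pk]));
        double f = std::exp(prop - th[pk]);
        double lr = 0.0;
        const std::vector<int> &cj = cyc_of_year[k];
        std::vector<double> newll(cj.size());
        for (size_t m = 0; m < cj.size(); ++m) {
          int j = cj[m];
          newll[m] = mod.cycle_ll(j, t50[j], scl[j] * f, sig);
          lr += newll[m] - llcyc[j];
        }
        lr += -0.5 * (prop * prop - th[pk] * th[pk]) / (sig_d * sig_d);
        if (adapt(pk, lr, it)) {
          for (size_t m = 0; m < cj.size(); ++m) {
            int j = cj[m]; scl[j] *= f; llcyc[j] = newll[m];
          }
          th[pk] = prop;
        }
      }
    }
    // --- hyper sds (log-scale RW; prior half-Normal, + log Jacobian) ---
    struct SdBlock { int ip, from, len; double s0; };
    SdBlock blocks[4] = { {2, iA, n_anim, s_a}, {3, iB, n_year, s_b},
                          {4, iC, n_anim, s_c}, {5, iD, n_year, s_d} };
    for (int bset = 0; bset < 4; ++bset) {
      SdBlock bl = blocks[bset];
      double cur = th[bl.ip];
      double prop = cur + R::rnorm(0.0, std::exp(lstep[bl.ip]));
      if (prop < -12.0 || prop > 6.0) { adapt(bl.ip, -1e300, it); continue; }
      double scur = std::exp(cur), sprop = std::exp(prop);
      double ss = 0.0;
      for (int k = 0; k < bl.len; ++k) ss += th[bl.from + k] * th[bl.from + k];
      double lr = (-bl.len * std::log(sprop) - 0.5 * ss / (sprop * sprop)) -
                  (-bl.len * std::log(scur) - 0.5 * ss / (scur * scur));
      lr += half_normal_lp(sprop, bl.s0) - half_normal_lp(scur, bl.s0);
      lr += prop - cur;  // Jacobian of log transform
      if (adapt(bl.ip, lr, it)) th[bl.ip] = prop;
    }
    // --- sigma_obs ---
    {
      double cur = th[6];
      double prop = cur + R::rnorm(0.0, std::exp(lstep[6]));
      if (prop > -10.0 && prop < 1.0) {
        double sprop = std::exp(prop);
        double lr = 0.0;
        std::vector<double> newll(n_cyc);
        for (int j = 0; j < n_cyc; ++j) {
          newll[j] = mod.cycle_ll(j, t50[j], scl[j], sprop);
          lr += newll[j] - llcyc[j];
        }
        lr += half_normal_lp(sprop, s_obs) - half_normal_lp(sig, s_obs);
        lr += prop - cur;
        if (adapt(6, lr, it)) {
          th[6] = prop; sig = sprop;
          for (int j = 0; j < n_cyc; ++j) llcyc[j] = newll[j];
        }
      } else adapt(6, -1e300, it);
    }
    // --- interweaving translations ---
    // a shared shift delta between a hyper mean and its random-effect block
    // leaves every cycle's t50/scale (hence the likelihood) unchanged; its
    // conditional posterior is Gaussian, so it is drawn exactly. This
    // removes the slow random-walk drift along the mu + mean(effects) ridge.
    {
      auto translate = [&](int imu, double mu0, double sd_mu,
                           int from, int len, double sig_block) {
        double prec = 1.0 / (sd_mu * sd_mu) +
                      len / (sig_block * sig_block);
        double sum = 0.0;
        for (int k = 0; k < len; ++k) sum += th[from + k];
        double mean = ((mu0 - th[imu]) / (sd_mu * sd_mu) +
                       sum / (sig_block * sig_block)) / prec;
        double delta = R::rnorm(mean, std::sqrt(1.0 / prec));
        th[imu] += delta;
        for (int k = 0; k < len; ++k) th[from + k] -= delta;
      };
      translate(0, m0, sd_mu_t50, iA, n_anim, std::exp(th[2]));
      translate(0, m0, sd_mu_t50, iB, n_year, std::exp(th[3]));
      translate(1, nu0, sd_mu_ls, iC, n_anim, std::exp(th[4]));
      translate(1, nu0, sd_mu_ls, iD, n_year, std::exp(th[5]));
    }
    if (it >= warmup) {
      for (int k = 0; k < npar; ++k) draws(it - warmup, k) = th[k];
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector accrate(npar);
  for (int k = 0; k < npar; ++k)
    accrate[k] = tries[k] > 0 ? acc[k] / tries[k] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = accrate);
}
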