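#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared trial-loop machinery for the task likelihoods and simulators.
//
// Parameter slot layout used throughout (one row per subject-wave block):
//   0 alpha_imm, 1 alpha_del, 2 tau_imm, 3 tau_del, 4 rho_imm, 5 rho_del
// Heuristic models store their single strategy weight tau in both tau slots.
// Model codes: 0 = ws, 1 = wsls, 2 = value-based inverse-temperature
// family (signed outcome valence +1/-1, rho fixed 1), 3 = value-based
// outcome-sensitivity family (value target rho*r with r in {0,1}, tau
// fixed 1).
//
// Choice coding: 1 = contingent option, 0 = noncontingent, -1 = no response.
// Rewards are {0,1}; non-response trials carry no update and no likelihood.

static const double P_EPS = 1e-12;

inline double softmax_pair(double dv, double tau) {
  // p(chosen) for a value difference dv at inverse temperature tau,
  // evaluated through the overflow-safe difference form.
  double p = 1.0 / (1.0 + std::exp(-tau * dv));
  if (p < P_EPS) p = P_EPS;
  if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
  return p;
}

// Run one subject-wave block of trials; values/weights start fresh.
// Writes per-trial log-lik into ll (if non-null) and the pre-choice
// probability of the contingent option into pcont (if non-null).
// Returns the summed log-likelihood over valid trials.
static double run_block(const int* cue, const int* cond, const int* choice,
                        const int* reward, int len, const double* par,
                        int model_code, int n_cues,
                        double* ll, double* pcont) {
  std::vector<double> vc(n_cues), vn(n_cues);
  double init = (model_code >= 2) ? 0.0 : 0.5;
  for (int k = 0; k < n_cues; ++k) { vc[k] = init; vn[k] = init; }

  double total = 0.0;
  for (int t = 0; t < len; ++t) {
    int k = cue[t];
    int c = cond[t];  // 0 immediate, 1 delayed
    double tau = par[2 + c];
    double p = softmax_pair(vc[k] - vn[k], tau);
    if (pcont) pcont[t] = p;
    int ch = choice[t];
    if (ch < 0) {  // non-response: no likelihood term, no update
      if (ll) ll[t] = NA_REAL;
      continue;
    }
    double lt = std::log(ch == 1 ? p : 1.0 - p);
    if (ll) ll[t] = lt;
    total += lt;
    if (model_code >= 2) {
      // inverse-temperature family learns signed valence +1/-1;
      // outcome-sensitivity family learns the scaled reward event rho*r
      double a = par[0 + c], rho = par[4 + c];
      double target = (model_code == 2) ? (2.0 * reward[t] - 1.0)
                                        : rho * reward[t];
      if (ch == 1) vc[k] += a * (target - vc[k]);
      else         vn[k] += a * (target - vn[k]);
    } else if (reward[t] == 1) {        // win-stay (both heuristics)
      vc[k] = (ch == 1) ? 1.0 : 0.0;
      vn[k] = 1.0 - vc[k];
    } else if (model_code == 1) {       // lose-shift (wsls only)
      vc[k] = (ch == 1) ? 0.0 : 1.0;
      vn[k] = 1.0 - vc[k];
    } else {                            // ws after a loss: indifference
      vc[k] = 0.5; vn[k] = 0.5;
    }
  }
  return total;
}

// [[Rcpp::export]]
List cpp_pointwise_loglik(IntegerVector blk_start, IntegerVector blk_len,
                          IntegerVector cue, IntegerVector cond,
                          IntegerVector choice, IntegerVector reward,
                          NumericMatrix pars, int model_code, int n_cues) {
  int n = cue.size(), nblk = blk_start.size();
  NumericVector ll(n), pcont(n);
  for (int b = 0; b < nblk; ++b) {
    int s = blk_start[b], len = blk_len[b];
    double par[6];
    for (int j = 0; j < 6; ++j) par[j] = pars(b, j);
    run_block(&cue[s], &cond[s], &choice[s], &reward[s], len, par,
              model_code, n_cues, &ll[s], &pcont[s]);
  }
  return List::create(_["loglik"] = ll, _["p_contingent"] = pcont);
}

// Simulate one subject-wave block on a fixed reward schedule.
// sched(k, j) = 1 if the contingent option is rewarded at the j-th
// presentation of cue k (the noncontingent option then gets 1-sched).
// nonresp[t] = 1 marks a trial forced to be a non-response.
// [[Rcpp::export]]
List cpp_simulate_block(IntegerVector cue, IntegerVector cond,
                        IntegerMatrix sched, IntegerVector nonresp,
                        NumericVector par6, int model_code, int n_cues) {
  int len = cue.size();
  IntegerVector choice(len), reward(len);
  NumericVector pcont(len);
  std::vector<double> vc(n_cues), vn(n_cues);
  std::vector<int> seen(n_cues, 0);
  double init = (model_code >= 2) ? 0.0 : 0.5;
  for (int k = 0; k < n_cues; ++k) { vc[k] = init; vn[k] = init; }

  for (int t = 0; t < len; ++t) {
    int k = cue[t], c = cond[t];
    double p = softmax_pair(vc[k] - vn[k], par6[2 + c]);
    pcont[t] = p;
    int j = seen[k]++;  // presentation index consumes the schedule slot
    if (nonresp[t] == 1) {
      choice[t] = -1;
      reward[t] = NA_INTEGER;
      continue;
    }
    int ch = (unif_rand() < p) ? 1 : 0;
    int r = (ch == 1) ? sched(k, j) : 1 - sched(k, j);
    choice[t] = ch;
    reward[t] = r;
    if (model_code >= 2) {
      double a = par6[0 + c], rho = par6[4 + c];
      double target = (model_code == 2) ? (2.0 * r - 1.0) : rho * r;
      if (ch == 1) vc[k] += a * (target - vc[k]);
      else         vn[k] += a * (target - vn[k]);
    } else if (r == 1) {
      vc[k] = (ch == 1) ? 1.0 : 0.0;
      vn[k] = 1.0 - vc[k];
    } else if (model_code == 1) {
      vc[k] = (ch == 1) ? 0.0 : 1.0;
      vn[k] = 1.0 - vc[k];
    } else {
      vc[k] = 0.5; vn[k] = 0.5;
    }
  }
  return List::create(_["choice"] = choice, _["reward"] = reward,
                      _["p_contingent"] = pcont);
}

// Monte-Carlo learning-score map for the single-alpha single-tau
// value-based model: each cell simulates `reps` datasets of
// n_cues x trials_per_cue trials on exact n_reward-of-trials_per_cue
// schedules and averages the latent contingent-choice probability.
// [[Rcpp::export]]
List cpp_learning_map(NumericVector alphas, NumericVector taus, int reps,
                      int n_cues, int trials_per_cue, int n_reward) {
  int na = alphas.size(), nt = taus.size();
  NumericMatrix score(na, nt), se(na, nt);
  std::vector<int> sched(trials_per_cue);
  double n_trials = (double) n_cues * trials_per_cue;

  for (int ia = 0; ia < na; ++ia) {
    double a = alphas[ia];
    for (int it = 0; it < nt; ++it) {
      double tau = taus[it];
      double mean = 0.0, m2 = 0.0;
      for (int rep = 0; rep < reps; ++rep) {
        double acc = 0.0;
        for (int k = 0; k < n_cues; ++k) {
          // fresh exact reward schedule per cue per replicate
          for (int j = 0; j < trials_per_cue; ++j)
            sched[j] = (j < n_reward) ? 1 : 0;
          for (int j = trials_per_cue - 1; j > 0; --j) {
            int u = (int) std::floor(unif_rand() * (j + 1));
            int tmp = sched[j]; sched[j] = sched[u]; sched[u] = tmp;
          }
          double v1 = 0.0, v0 = 0.0;
          for (int j = 0; j < trials_per_cue; ++j) {
            double p = softmax_pair(v1 - v0, tau);
            acc += p;
            int ch = (unif_rand() < p) ? 1 : 0;
            double val = (ch == 1) ? 2.0 * sched[j] - 1.0
                                   : 1.0 - 2.0 * sched[j];
            if (ch == 1) v1 += a * (val - v1);
            else         v0 += a * (val - v0);
          }
        }
        double x = acc / n_trials;
        double d = x - mean;      // Welford over replicates
        mean += d / (rep + 1);
        m2 += d * (x - mean);
      }
      score(ia, it) = mean;
      se(ia, it) = (reps > 1) ? std::sqrt(m2 / (reps - 1) / reps) : NA_REAL;
    }
  }
  return List::create(_["score"] = score, _["se"] = se);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: adaptive Metropolis-within-Gibbs on the
// non-centered parameterisation, interleaved with centered-coordinate
// (likelihood-invariant) moves for the group-level location/scale/
// correlation to keep mixing healthy when the data are informative.
//
// Model, per free parameter p and wave w:
//   mu[p][w]    ~ Normal(0, loc_sd)
//   sigma[p][w] ~ half-Normal(0, scale_sd)            (eta = log sigma)
//   r[p]        ~ LKJ(2) on the 2x2 cross-wave block  (y = atanh r)
//   z[i][p][.]  ~ Normal(0, I2);  e = L_p z,  L = [[1,0],[r,sqrt(1-r^2)]]
//   theta[i][p][w] = lower + (upper-lower) * Phi(mu + sigma * e_w)
// ---------------------------------------------------------------------------

struct HierModel {
  // data
  const int *cue, *cond, *choice, *reward;
  std::vector<int> blk_start, blk_len, sub_of_blk, wave_of_blk;
  std::vector<std::vector<int> > blocks_of_sub;
  int n_sub, n_blk, n_trials, n_cues, model_code, P;
  std::vector<double> lower, upper, base6;
  std::vector<int> map6;  // 6 x P, column-major: map6[s + 6*p]
  double loc_sd, scale_sd;

  // state
  std::vector<double> mu, eta, y;   // mu,eta: P*2 ([p*2+w]); y: P
  std::vector<double> z;            // n_sub * 2P: z[i*2P + 2p + w]
  std::vector<double> cur_bll;      // per-block log-lik

  void theta_block(int b, double* par6) const {
    int i = sub_of_blk[b], w = wave_of_blk[b];
    for (int s = 0; s < 6; ++s) par6[s] = base6[s];
    for (int p = 0; p < P; ++p) {
      double rr = std::tanh(y[p]);
      double z0 = z[i * 2 * P + 2 * p], z1 = z[i * 2 * P + 2 * p + 1];
      double e = (w == 0) ? z0 : rr * z0 + std::sqrt(1.0 - rr * rr) * z1;
      double x = mu[p * 2 + w] + std::exp(eta[p * 2 + w]) * e;
      double th = lower[p] + (upper[p] - lower[p]) * R::pnorm(x, 0.0, 1.0, 1, 0);
      for (int s = 0; s < 6; ++s)
        if (map6[s + 6 * p]) par6[s] = th;
    }
  }

  double block_ll(int b) const {
    double par6[6];
    theta_block(b, par6);
    int s = blk_start[b];
    return run_block(cue + s, cond + s, choice + s, reward + s, blk_len[b],
                     par6, model_code, n_cues, 0, 0);
  }

  double lp_mu1(double m) const { return R::dnorm(m, 0.0, loc_sd, 1); }
  double lp_eta1(double e) const {
    double s = std::exp(e);
    return R::dnorm(s, 0.0, scale_sd, 1) + e;  // half-normal + log-jacobian
  }
  double lp_y1(double yy) const {
    double rr = std::tanh(yy);
    // LKJ(2) density (1-r^2)^(eta-1) with eta=2, plus tanh jacobian (1-r^2)
    return 2.0 * std::log1p(-rr * rr);
  }
};

// 1-D slice sampler (Neal 2003): stepping out + shrinkage.
template <class F>
static double slice1d(double x0, F logf, double w) {
  double logy = logf(x0) + std::log(unif_rand());
  double u = unif_rand() * w;
  double L = x0 - u, R = x0 + (w - u);
  int j = (int) std::floor(20.0 * unif_rand());
  int k = 19 - j;
  while (j-- > 0 && logf(L) > logy) L -= w;
  while (k-- > 0 && logf(R) > logy) R += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = L + unif_rand() * (R - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

inline double mh_accept(double delta) {
  return (delta >= 0.0) ? 1.0 : std::exp(delta);
}

// [[Rcpp::export]]
List cpp_fit_hier(IntegerVector blk_start, IntegerVector blk_len,
                  IntegerVector sub_of_blk, IntegerVector wave_of_blk,
                  IntegerVector cue, IntegerVector cond,
                  IntegerVector choice, IntegerVector reward,
                  int n_sub, int n_cues, int model_code,
                  NumericVector lower, NumericVector upper,
                  IntegerMatrix par_map, NumericVector par_base,
                  double loc_sd, double scale_sd,
                  int n_iter, int n_warmup, int thin_ll,
                  NumericVector mu0, NumericVector eta0, NumericVector y0,
                  NumericVector z0) {
  HierModel M;
  bool has_data = cue.size() > 0;
  M.cue = has_data ? &cue[0] : 0;
  M.cond = has_data ? &cond[0] : 0;
  M.choice = has_data ? &choice[0] : 0;
  M.reward = has_data ? &reward[0] : 0;
  M.blk_start = as<std::vector<int> >(blk_start);
  M.blk_len = as<std::vector<int> >(blk_len);
  M.sub_of_blk = as<std::vector<int> >(sub_of_blk);
  M.wave_of_blk = as<std::vector<int> >(wave_of_blk);
  M.n_sub = n_sub; M.n_blk = blk_start.size(); M.n_trials = cue.size();
  M.n_cues = n_cues; M.model_code = model_code;
  M.P = lower.size();
  M.lower = as<std::vector<double> >(lower);
  M.upper = as<std::vector<double> >(upper);
  M.base6 = as<std::vector<double> >(par_base);
  M.map6.resize(6 * M.P);
  for (int p = 0; p < M.P; ++p)
    for (int s = 0; s < 6; ++s) M.map6[s + 6 * p] = par_map(s, p);
  M.loc_sd = loc_sd; M.scale_sd = scale_sd;
  M.mu = as<std::vector<double> >(mu0);
  M.eta = as<std::vector<double> >(eta0);
  M.y = as<std::vector<double> >(y0);
  M.z = as<std::vector<double> >(z0);

  const int P = M.P, P2 = 2 * P;
  M.blocks_of_sub.assign(n_sub, std::vector<int>());
  for (int b = 0; b < M.n_blk; ++b) M.blocks_of_sub[M.sub_of_blk[b]].push_back(b);
  M.cur_bll.resize(M.n_blk);
  for (int b = 0; b < M.n_blk; ++b) M.cur_bll[b] = M.block_ll(b);

  // adaptive proposal log-scales (subject x parameter x wave for z)
  std::vector<double> ls_z0((size_t) n_sub * P, std::log(0.2));
  std::vector<double> ls_z1((size_t) n_sub * P, std::log(0.2));
  std::vector<double> ls_mu(P2, std::log(0.10)), ls_eta(P2, std::log(0.10));
  std::vector<double> ls_y(P, std::log(0.20));
  const double tgt_sca = 0.44;

  int n_save = n_iter - n_warmup;
  int n_keep = (n_save + thin_ll - 1) / thin_ll;
  NumericMatrix mu_save(n_save, P2), sigma_save(n_save, P2), r_save(n_save, P);
  NumericMatrix theta_save(n_save, n_sub * P2);
  NumericMatrix ll_save(n_keep, M.n_trials);
  NumericVector total_ll_save(n_save);
  int kept = 0;

  std::vector<double> znew(P2), bll_new(2);

  for (int t = 1; t <= n_iter; ++t) {
    double adapt = (t <= n_warmup) ? std::pow((double) t, -0.6) : 0.0;

    // --- subject-level z updates: the raw wave-1 coordinate and the
    //     wave-2 innovation get separately adapted random-walk scales
    //     (identification is strongly anisotropic across waves), plus a
    //     prior independence proposal that decorrelates weakly
    //     identified subject effects in a single move ---
    for (int sweep = 0; sweep < 2; ++sweep)
    for (int i = 0; i < n_sub; ++i) {
      const std::vector<int>& bs = M.blocks_of_sub[i];
      std::vector<double> newll(bs.size());
      for (int p = 0; p < P; ++p) {
        // z0: enters both waves (wave 2 through the correlation)
        double z0 = M.z[i * P2 + 2 * p];
        double n0 = z0 + std::exp(ls_z0[(size_t) i * P + p]) * norm_rand();
        double dprior = 0.5 * (z0 * z0 - n0 * n0);
        M.z[i * P2 + 2 * p] = n0;
        double dll = 0.0;
        for (size_t q = 0; q < bs.size(); ++q) {
          newll[q] = M.block_ll(bs[q]);
          dll += newll[q] - M.cur_bll[bs[q]];
        }
        double ap = mh_accept(dprior + dll);
        if (unif_rand() < ap) {
          for (size_t q = 0; q < bs.size(); ++q) M.cur_bll[bs[q]] = newll[q];
        } else {
          M.z[i * P2 + 2 * p] = z0;
        }
        if (adapt > 0.0) ls_z0[(size_t) i * P + p] += adapt * (ap - tgt_sca);
        // z1: wave-2 innovation only
        double z1 = M.z[i * P2 + 2 * p + 1];
        double n1 = z1 + std::exp(ls_z1[(size_t) i * P + p]) * norm_rand();
        dprior = 0.5 * (z1 * z1 - n1 * n1);
        M.z[i * P2 + 2 * p + 1] = n1;
        dll = 0.0;
        for (size_t q = 0; q < bs.size(); ++q) {
          if (M.wave_of_blk[bs[q]] != 1) { newll[q] = M.cur_bll[bs[q]]; continue; }
          newll[q] = M.block_ll(bs[q]);
          dll += newll[q] - M.cur_bll[bs[q]];
        }
        ap = mh_accept(dprior + dll);
        if (unif_rand() < ap) {
          for (size_t q = 0; q < bs.size(); ++q) M.cur_bll[bs[q]] = newll[q];
        } else {
          M.z[i * P2 + 2 * p + 1] = z1;
        }
        if (adapt > 0.0) ls_z1[(size_t) i * P + p] += adapt * (ap - tgt_sca);
        // joint independence proposal from the N(0, I2) prior
        z0 = M.z[i * P2 + 2 * p]; z1 = M.z[i * P2 + 2 * p + 1];
        M.z[i * P2 + 2 * p] = norm_rand();
        M.z[i * P2 + 2 * p + 1] = norm_rand();
        dll = 0.0;
        for (size_t q = 0; q < bs.size(); ++q) {
          newll[q] = M.block_ll(bs[q]);
          dll += newll[q] - M.cur_bll[bs[q]];
        }
        if (unif_rand() < mh_accept(dll)) {
          for (size_t q = 0; q < bs.size(); ++q) M.cur_bll[bs[q]] = newll[q];
        } else {
          M.z[i * P2 + 2 * p] = z0; M.z[i * P2 + 2 * p + 1] = z1;
        }
      }
    }

    // --- non-centered group updates (data-informed; thetas move) ---
    for (int grep = 0; grep < 4; ++grep)
    for (int p = 0; p < P; ++p) {
      for (int w = 0; w < 2; ++w) {
        int j = p * 2 + w;
        // mu
        double old = M.mu[j];
        M.mu[j] = old + std::exp(ls_mu[j]) * norm_rand();
        double d = M.lp_mu1(M.mu[j]) - M.lp_mu1(old), dll = 0.0;
        std::vector<double> nl(M.n_blk, NA_REAL);
        for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == w) {
          nl[b] = M.block_ll(b); dll += nl[b] - M.cur_bll[b];
        }
        double ap = mh_accept(d + dll);
        if (unif_rand() < ap) {
          for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == w) M.cur_bll[b] = nl[b];
        } else M.mu[j] = old;
        if (adapt > 0.0) ls_mu[j] += adapt * (ap - tgt_sca);
        // eta
        old = M.eta[j];
        M.eta[j] = old + std::exp(ls_eta[j]) * norm_rand();
        d = M.lp_eta1(M.eta[j]) - M.lp_eta1(old); dll = 0.0;
        for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == w) {
          nl[b] = M.block_ll(b); dll += nl[b] - M.cur_bll[b];
        }
        ap = mh_accept(d + dll);
        if (unif_rand() < ap) {
          for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == w) M.cur_bll[b] = nl[b];
        } else M.eta[j] = old;
        if (adapt > 0.0) ls_eta[j] += adapt * (ap - tgt_sca);
      }
      // correlation (affects wave-2 effects through L)
      double old = M.y[p];
      M.y[p] = old + std::exp(ls_y[p]) * norm_rand();
      double d = M.lp_y1(M.y[p]) - M.lp_y1(old), dll = 0.0;
      std::vector<double> nl(M.n_blk, NA_REAL);
      for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == 1) {
        nl[b] = M.block_ll(b); dll += nl[b] - M.cur_bll[b];
      }
      double ap = mh_accept(d + dll);
      if (unif_rand() < ap) {
        for (int b = 0; b < M.n_blk; ++b) if (M.wave_of_blk[b] == 1) M.cur_bll[b] = nl[b];
      } else M.y[p] = old;
      if (adapt > 0.0) ls_y[p] += adapt * (ap - tgt_sca);
    }

    // --- centered-coordinate interweaving updates (likelihood-invariant):
    //     with every subject's unconstrained effect x = mu + sigma * e held
    //     fixed, the 1-D conditionals of each group location, log-scale and
    //     correlation cost O(n_sub); draw each exactly by slice sampling,
    //     then rewrite z from the fixed effects.
    if (n_sub > 0) for (int p = 0; p < P; ++p) {
      double rr = std::tanh(M.y[p]);
      double s1mr = std::sqrt(1.0 - rr * rr);
      double sig0 = std::exp(M.eta[p * 2]), sig1 = std::exp(M.eta[p * 2 + 1]);
      std::vector<double> x0(n_sub), x1(n_sub);
      for (int i = 0; i < n_sub; ++i) {
        double z0 = M.z[i * P2 + 2 * p], z1 = M.z[i * P2 + 2 * p + 1];
        x0[i] = M.mu[p * 2] + sig0 * z0;
        x1[i] = M.mu[p * 2 + 1] + sig1 * (rr * z0 + s1mr * z1);
      }
      double mu0 = M.mu[p * 2], mu1 = M.mu[p * 2 + 1];
      double le0 = M.eta[p * 2], le1 = M.eta[p * 2 + 1];
      double yc = M.y[p];
      // log N(0,I2) prior of the implied z pair, x held fixed
      auto zquad = [&](double m0, double m1, double lsg0, double lsg1,
                       double yy) {
        double r = std::tanh(yy), s = std::sqrt(1.0 - r * r);
        double s0 = std::exp(lsg0), s1 = std::exp(lsg1);
        double q = 0.0;
        for (int i = 0; i < n_sub; ++i) {
          double e0 = (x0[i] - m0) / s0, e1 = (x1[i] - m1) / s1;
          double z1c = (e1 - r * e0) / s;
          q += e0 * e0 + z1c * z1c;
        }
        return -0.5 * q;
      };
      mu0 = slice1d(mu0, [&](double v) {
        return M.lp_mu1(v) + zquad(v, mu1, le0, le1, yc); }, 0.3);
      mu1 = slice1d(mu1, [&](double v) {
        return M.lp_mu1(v) + zquad(mu0, v, le0, le1, yc); }, 0.3);
      le0 = slice1d(le0, [&](double v) {     // -n*eta from |dz/dx|
        return M.lp_eta1(v) - n_sub * v + zquad(mu0, mu1, v, le1, yc); }, 0.5);
      le1 = slice1d(le1, [&](double v) {
        return M.lp_eta1(v) - n_sub * v + zquad(mu0, mu1, le0, v, yc); }, 0.5);
      yc = slice1d(yc, [&](double v) {       // -n*log sqrt(1-r^2) likewise
        double r = std::tanh(v);
        return M.lp_y1(v) - 0.5 * n_sub * std::log1p(-r * r)
               + zquad(mu0, mu1, le0, le1, v); }, 0.5);
      M.mu[p * 2] = mu0; M.mu[p * 2 + 1] = mu1;
      M.eta[p * 2] = le0; M.eta[p * 2 + 1] = le1;
      M.y[p] = yc;
      double rn = std::tanh(yc), sn = std::sqrt(1.0 - rn * rn);
      double s0n = std::exp(le0), s1n = std::exp(le1);
      for (int i = 0; i < n_sub; ++i) {
        double e0 = (x0[i] - mu0) / s0n, e1 = (x1[i] - mu1) / s1n;
        M.z[i * P2 + 2 * p] = e0;
        M.z[i * P2 + 2 * p + 1] = (e1 - rn * e0) / sn;
      }
    }

    // --- save ---
    if (t > n_warmup) {
      int it = t - n_warmup - 1;
      double total = 0.0;
      for (int b = 0; b < M.n_blk; ++b) total += M.cur_bll[b];
      total_ll_save[it] = total;
      for (int j = 0; j < P2; ++j) {
        mu_save(it, j) = M.mu[j];
        sigma_save(it, j) = std::exp(M.eta[j]);
      }
      for (int p = 0; p < P; ++p) r_save(it, p) = std::tanh(M.y[p]);
      double par6[6];
      for (int i = 0; i < n_sub; ++i) {
        for (int w = 0; w < 2; ++w) {
          // bounded individual parameters for every subject-wave (latent
          // waves included); column layout i + n_sub*(w + 2*p) so the R
          // side can reshape into an (iter, subject, wave, param) array
          for (int p = 0; p < P; ++p) {
            double rr = std::tanh(M.y[p]);
            double z0 = M.z[i * P2 + 2 * p], z1 = M.z[i * P2 + 2 * p + 1];
            double e = (w == 0) ? z0 : rr * z0 + std::sqrt(1.0 - rr * rr) * z1;
            double x = M.mu[p * 2 + w] + std::exp(M.eta[p * 2 + w]) * e;
            theta_save(it, i + n_sub * (w + 2 * p)) =
              M.lower[p] + (M.upper[p] - M.lower[p]) * R::pnorm(x, 0.0, 1.0, 1, 0);
          }
        }
      }
      if (it % thin_ll == 0) {
        for (int b = 0; b < M.n_blk; ++b) {
          M.theta_block(b, par6);
          int s = M.blk_start[b];
          std::vector<double> llbuf(M.blk_len[b]);
          run_block(M.cue + s, M.cond + s, M.choice + s, M.reward + s,
                    M.blk_len[b], par6, M.model_code, M.n_cues, &llbuf[0], 0);
          for (int q = 0; q < M.blk_len[b]; ++q) ll_save(kept, s + q) = llbuf[q];
        }
        ++kept;
      }
    }
  }

  double final_total = 0.0;
  for (int b = 0; b < M.n_blk; ++b) final_total += M.cur_bll[b];

  return List::create(
    _["mu"] = mu_save, _["sigma"] = sigma_save, _["r"] = r_save,
    _["theta"] = theta_save, _["log_lik"] = ll_save,
    _["total_ll"] = total_ll_save, _["final_total_ll"] = final_total,
    _["n_kept_ll"] = kept);
}
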