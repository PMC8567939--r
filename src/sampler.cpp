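// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// meal-response model.
//
// Model (per patient p, observation i, meal m):
//   y_i ~ Normal(b_p + sum_m beta_p c_m exp(-(t_i - r_m - d_m)^2 / (2 a_p^2)),
//                sigma_p)
//   beta_p ~ Normal+(beta_g, sd_beta);  log a_p ~ Normal(log alpha_g, sd_alpha)
//   b_p ~ Normal+(b_loc, b_scale);      sigma_p ~ half-Normal(noise_scale)
//   d_m ~ Normal(0, jitter_sd) truncated to |d| <= offset_max
// Hyperpriors: beta_g ~ Normal+(loc, scale); log alpha_g ~ Normal;
//   sd_beta, sd_alpha ~ half-Normal.
//
// Positive scale parameters are sampled on the log scale (Jacobian terms
// included); beta_p, beta_g, b_p, d_m are sampled on the natural scale
// with out-of-support proposals rejected. Likelihood updates are
// incremental: the N x M basis matrix is cached and only the affected
// column (offset move) or nothing (beta / baseline / sigma move) is
// recomputed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }
static inline double log_pnorm(double x) { return R::pnorm(x, 0.0, 1.0, 1, 1); }

struct Pat {
  int N, M;
  std::vector<double> t, y, c, r;
  double beta, la, alpha, b, lsig, sig;
  std::vector<double> delta;
  std::vector<double> B;  // N x M, column-major
  std::vector<double> s;  // B * c
  double SSR;
  // adaptive log step sizes
  double ls_beta, ls_la, ls_b, ls_lsig, ls_delta, ls_joint, ls_bb;
};

static void recompute_basis(Pat &p) {
  std::fill(p.s.begin(), p.s.end(), 0.0);
  for (int m = 0; m < p.M; ++m) {
    double tau = p.r[m] + p.delta[m];
    double inv = 1.0 / (2.0 * sq(p.alpha));
    double *col = &p.B[(size_t)m * p.N];
    for (int i = 0; i < p.N; ++i) {
      col[i] = std::exp(-sq(p.t[i] - tau) * inv);
      p.s[i] += p.c[m] * col[i];
    }
  }
  p.SSR = 0.0;
  for (int i = 0; i < p.N; ++i) p.SSR += sq(p.y[i] - p.b - p.beta * p.s[i]);
}

static double ssr_with(const Pat &p, double beta, double b,
                       const std::vector<double> &s) {
  double ssr = 0.0;
  for (int i = 0; i < p.N; ++i) ssr += sq(p.y[i] - b - beta * s[i]);
  return ssr;
}

struct Chain {
  double beta_g, lag, lsdb, lsda;
  double ls_bg, ls_lag, ls_lsdb, ls_lsda, ls_iwb, ls_iwa;
};

// [[Rcpp::export]]
List mwg_sample(List patients, List prior, List control) {
  const double bg_loc = as<double>(prior["beta_g_loc"]);
  const double bg_scale = as<double>(prior["beta_g_scale"]);
  const double lag_loc = std::log(as<double>(prior["alpha_g_loc"]));
  const double lag_scale = as<double>(prior["alpha_g_scale"]);
  const double b_loc = as<double>(prior["baseline_loc"]);
  const double b_scale = as<double>(prior["baseline_scale"]);
  const double ns = as<double>(prior["noise_scale"]);
  const double sdb_scale = as<double>(prior["sd_beta_scale"]);
  const double sda_scale = as<double>(prior["sd_alpha_scale"]);
  const double jit = as<double>(prior["jitter_sd"]);
  const double dmax = as<double>(prior["offset_max"]);

  const int n_chains = as<int>(control["chains"]);
  const int warmup = as<int>(control["warmup"]);
  const int iter = as<int>(control["iter"]);
  const bool est_off = as<bool>(control["estimate_offsets"]) && jit > 0;
  const double target = 0.44;

  const int P = patients.size();
  std::vector<Pat> base(P);
  int n_par = 4;
  for (int p = 0; p < P; ++p) {
    List pl = patients[p];
    Pat &pt = base[p];
    pt.t = as<std::vector<double> >(pl["t"]);
    pt.y = as<std::vector<double> >(pl["y"]);
    pt.c = as<std::vector<double> >(pl["carbs"]);
    pt.r = as<std::vector<double> >(pl["rtimes"]);
    pt.N = (int)pt.t.size();
    pt.M = (int)pt.c.size();
    pt.B.assign((size_t)pt.N * pt.M, 0.0);
    pt.s.assign(pt.N, 0.0);
    pt.delta.assign(pt.M, 0.0);
    n_par += 4 + pt.M;
  }

  List chains_out(n_chains);
  std::vector<double> s_prop, col_prop;

  for (int ch = 0; ch < n_chains; ++ch) {
    // dispersed initial values
    Chain G;
    G.beta_g = std::fabs(bg_loc + 0.5 * bg_scale * norm_rand()) + 1e-4;
    G.lag = lag_loc + 0.25 * norm_rand();
    G.lsdb = std::log(sdb_scale * (0.3 + 0.5 * unif_rand()));
    G.lsda = std::log(sda_scale * (0.3 + 0.5 * unif_rand()));
    G.ls_bg = std::log(0.01); G.ls_lag = std::log(0.1);
    G.ls_lsdb = std::log(0.3); G.ls_lsda = std::log(0.3);
    G.ls_iwb = std::log(0.3); G.ls_iwa = std::log(0.3);

    std::vector<Pat> pats = base;
    for (int p = 0; p < P; ++p) {
      Pat &pt = pats[p];
      List pl = patients[p];
      pt.beta = std::fabs(G.beta_g + 0.01 * norm_rand()) + 1e-5;
      pt.la = G.lag + 0.2 * norm_rand();
      pt.alpha = std::exp(pt.la);
      pt.b = as<double>(pl["init_baseline"]) * std::exp(0.02 * norm_rand());
      pt.lsig = std::log(as<double>(pl["init_sigma"])) + 0.2 * norm_rand();
      pt.sig = std::exp(pt.lsig);
      std::fill(pt.delta.begin(), pt.delta.end(), 0.0);
      recompute_basis(pt);
      pt.ls_beta = std::log(0.01); pt.ls_la = std::log(0.1);
      pt.ls_b = std::log(0.05); pt.ls_lsig = std::log(0.1);
      pt.ls_delta = std::log(5.0); pt.ls_joint = std::log(0.1);
      pt.ls_bb = std::log(0.05);
    }

    NumericMatrix draws(iter, n_par);
    const int total = warmup + iter;

    for (int it = 0; it < total; ++it) {
      const bool adapting = it < warmup;
      const double gam = adapting ? 1.0 / std::pow(it / 50.0 + 1.0, 0.6) : 0.0;
      const double sdb = std::exp(G.lsdb), sda = std::exp(G.lsda);

      // --- group-level updates (prior terms only) ---
      // beta_g
      {
        double prop = G.beta_g + std::exp(G.ls_bg) * norm_rand();
        double acc = 0.0;
        if (prop >= 0.0) {
          double d = -0.5 * (sq((prop - bg_loc) / bg_scale) -
                             sq((G.beta_g - bg_loc) / bg_scale));
          d -= P * (log_pnorm(prop / sdb) - log_pnorm(G.beta_g / sdb));
          for (int p = 0; p < P; ++p)
            d -= 0.5 * (sq((pats[p].beta - prop) / sdb) -
                        sq((pats[p].beta - G.beta_g) / sdb));
          acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) G.beta_g = prop;
        }
        if (adapting) G.ls_bg += gam * (acc - target);
      }
      // log alpha_g
      {
        double prop = G.lag + std::exp(G.ls_lag) * norm_rand();
        double d = -0.5 * (sq((prop - lag_loc) / lag_scale) -
                           sq((G.lag - lag_loc) / lag_scale));
        for (int p = 0; p < P; ++p)
          d -= 0.5 * (sq((pats[p].la - prop) / sda) -
                      sq((pats[p].la - G.lag) / sda));
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) G.lag = prop;
        if (adapting) G.ls_lag += gam * (acc - target);
      }
      // log sd_beta
      {
        double prop = G.lsdb + std::exp(G.ls_lsdb) * norm_rand();
        double sp = std::exp(prop);
        double d = -0.5 * (sq(sp / sdb_scale) - sq(sdb / sdb_scale)) +
                   (prop - G.lsdb);  // half-normal prior + Jacobian
        d -= P * ((std::log(sp) + log_pnorm(G.beta_g / sp)) -
                  (std::log(sdb) + log_pnorm(G.beta_g / sdb)));
        for (int p = 0; p < P; ++p)
          d -= 0.5 * sq(pats[p].beta - G.beta_g) * (1.0 / sq(sp) - 1.0 / sq(sdb));
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) G.lsdb = prop;
        if (adapting) G.ls_lsdb += gam * (acc - target);
      }
      // log sd_alpha
      {
        double sda_cur = std::exp(G.lsda);
        double prop = G.lsda + std::exp(G.ls_lsda) * norm_rand();
        double sp = std::exp(prop);
        double d = -0.5 * (sq(sp / sda_scale) - sq(sda_cur / sda_scale)) +
                   (prop - G.lsda);
        d -= P * (std::log(sp) - std::log(sda_cur));
        for (int p = 0; p < P; ++p)
          d -= 0.5 * sq(pats[p].la - G.lag) * (1.0 / sq(sp) - 1.0 / sq(sda_cur));
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) G.lsda = prop;
        if (adapting) G.ls_lsda += gam * (acc - target);
      }

      // interweaving rescale move for sd_beta: scale the spread and the
      // patient deviations together (beta_p' = beta_g + (beta_p -
      // beta_g) e^eps, sd_beta' = sd_beta e^eps). The hierarchy
      // quadratics are invariant and the patient-count log-sd terms
      // cancel against the Jacobian, leaving likelihood + hyperprior +
      // truncation terms. This breaks the funnel between the spread and
      // the patient-level values.
      {
        double sdb_c = std::exp(G.lsdb);
        double eps = std::exp(G.ls_iwb) * norm_rand();
        double lsdb_p = G.lsdb + eps, sdb_p = std::exp(lsdb_p);
        std::vector<double> bprop(P), ssrp(P);
        bool ok = true;
        double d = -0.5 * (sq(sdb_p / sdb_scale) - sq(sdb_c / sdb_scale)) +
                   eps -
                   P * (log_pnorm(G.beta_g / sdb_p) -
                        log_pnorm(G.beta_g / sdb_c));
        for (int p = 0; p < P && ok; ++p) {
          bprop[p] = G.beta_g + (pats[p].beta - G.beta_g) * std::exp(eps);
          if (bprop[p] < 0) { ok = false; break; }
          ssrp[p] = ssr_with(pats[p], bprop[p], pats[p].b, pats[p].s);
          d -= (ssrp[p] - pats[p].SSR) / (2.0 * sq(pats[p].sig));
        }
        double acc = 0.0;
        if (ok) {
          acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) {
            G.lsdb = lsdb_p;
            for (int p = 0; p < P; ++p) {
              pats[p].beta = bprop[p]; pats[p].SSR = ssrp[p];
            }
          }
        }
        if (adapting) G.ls_iwb += gam * (acc - target);
      }
      // the same rescale move for sd_alpha and the log length-scales
      {
        double sda_c = std::exp(G.lsda);
        double eps = std::exp(G.ls_iwa) * norm_rand();
        double lsda_p = G.lsda + eps, sda_p = std::exp(lsda_p);
        std::vector<double> laprop(P), ssrp(P);
        double d = -0.5 * (sq(sda_p / sda_scale) - sq(sda_c / sda_scale)) +
                   eps;
        for (int p = 0; p < P; ++p) {
          Pat &pt = pats[p];
          laprop[p] = G.lag + (pt.la - G.lag) * std::exp(eps);
          double alpha_p = std::exp(laprop[p]);
          double inv = 1.0 / (2.0 * sq(alpha_p));
          s_prop.assign(pt.N, 0.0);
          for (int m = 0; m < pt.M; ++m) {
            double tau = pt.r[m] + pt.delta[m];
            for (int i = 0; i < pt.N; ++i)
              s_prop[i] += pt.c[m] * std::exp(-sq(pt.t[i] - tau) * inv);
          }
          ssrp[p] = ssr_with(pt, pt.beta, pt.b, s_prop);
          d -= (ssrp[p] - pt.SSR) / (2.0 * sq(pt.sig));
        }
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) {
          G.lsda = lsda_p;
          for (int p = 0; p < P; ++p) {
            pats[p].la = laprop[p];
            pats[p].alpha = std::exp(laprop[p]);
            pats[p].SSR = ssrp[p];
            recompute_basis(pats[p]);
          }
        }
        if (adapting) G.ls_iwa += gam * (acc - target);
      }

      const double sdb2 = std::exp(G.lsdb), sda2 = std::exp(G.lsda);

      // --- patient-level updates ---
      for (int p = 0; p < P; ++p) {
        Pat &pt = pats[p];
        double inv2s2 = 1.0 / (2.0 * sq(pt.sig));

        // beta
        {
          double prop = pt.beta + std::exp(pt.ls_beta) * norm_rand();
          double acc = 0.0;
          if (prop >= 0.0) {
            double ssr = ssr_with(pt, prop, pt.b, pt.s);
            double d = -(ssr - pt.SSR) * inv2s2 -
                       0.5 * (sq((prop - G.beta_g) / sdb2) -
                              sq((pt.beta - G.beta_g) / sdb2));
            acc = d >= 0 ? 1.0 : std::exp(d);
            if (unif_rand() < acc) { pt.beta = prop; pt.SSR = ssr; }
          }
          if (adapting) pt.ls_beta += gam * (acc - target);
        }
        // log alpha (full basis recompute)
        {
          double prop = pt.la + std::exp(pt.ls_la) * norm_rand();
          double alpha_p = std::exp(prop);
          double inv = 1.0 / (2.0 * sq(alpha_p));
          s_prop.assign(pt.N, 0.0);
          col_prop.resize((size_t)pt.N * pt.M);
          for (int m = 0; m < pt.M; ++m) {
            double tau = pt.r[m] + pt.delta[m];
            double *col = &col_prop[(size_t)m * pt.N];
            for (int i = 0; i < pt.N; ++i) {
              col[i] = std::exp(-sq(pt.t[i] - tau) * inv);
              s_prop[i] += pt.c[m] * col[i];
            }
          }
          double ssr = ssr_with(pt, pt.beta, pt.b, s_prop);
          double d = -(ssr - pt.SSR) * inv2s2 -
                     0.5 * (sq((prop - G.lag) / sda2) -
                            sq((pt.la - G.lag) / sda2));
          double acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) {
            pt.la = prop; pt.alpha = alpha_p; pt.SSR = ssr;
            pt.s.swap(s_prop); pt.B.swap(col_prop);
          }
          if (adapting) pt.ls_la += gam * (acc - target);
        }
        // joint (log beta, log alpha) move along the constant-area
        // direction: height x width is tightly identified, the two
        // factors individually are not, so this decorrelates them
        if (pt.beta > 0) {
          double eps = std::exp(pt.ls_joint) * norm_rand();
          double bprop = pt.beta * std::exp(eps);
          double laprop = pt.la - eps;
          double alpha_p = std::exp(laprop);
          double inv = 1.0 / (2.0 * sq(alpha_p));
          s_prop.assign(pt.N, 0.0);
          col_prop.resize((size_t)pt.N * pt.M);
          for (int m = 0; m < pt.M; ++m) {
            double tau = pt.r[m] + pt.delta[m];
            double *col = &col_prop[(size_t)m * pt.N];
            for (int i = 0; i < pt.N; ++i) {
              col[i] = std::exp(-sq(pt.t[i] - tau) * inv);
              s_prop[i] += pt.c[m] * col[i];
            }
          }
          double ssr = ssr_with(pt, bprop, pt.b, s_prop);
          double d = -(ssr - pt.SSR) * inv2s2 -
                     0.5 * (sq((bprop - G.beta_g) / sdb2) -
                            sq((pt.beta - G.beta_g) / sdb2)) -
                     0.5 * (sq((laprop - G.lag) / sda2) -
                            sq((pt.la - G.lag) / sda2)) +
                     eps;  // Jacobian of the multiplicative beta proposal
          double acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) {
            pt.beta = bprop; pt.la = laprop; pt.alpha = alpha_p;
            pt.SSR = ssr; pt.s.swap(s_prop); pt.B.swap(col_prop);
          }
          if (adapting) pt.ls_joint += gam * (acc - target);
        }
        // baseline
        {
          double prop = pt.b + std::exp(pt.ls_b) * norm_rand();
          double acc = 0.0;
          if (prop > 0.0) {
            double ssr = ssr_with(pt, pt.beta, prop, pt.s);
            double d = -(ssr - pt.SSR) * inv2s2 -
                       0.5 * (sq((prop - b_loc) / b_scale) -
                              sq((pt.b - b_loc) / b_scale));
            acc = d >= 0 ? 1.0 : std::exp(d);
            if (unif_rand() < acc) { pt.b = prop; pt.SSR = ssr; }
          }
          if (adapting) pt.ls_b += gam * (acc - target);
        }
        // joint (baseline, beta) move: a higher baseline trades off
        // against lower bump heights; move along the least-squares
        // direction (s is unchanged by the move, so the map is the
        // same at the reverse proposal and the kernel stays symmetric)
        {
          double ss = 0.0, s2 = 0.0;
          for (int i = 0; i < pt.N; ++i) { ss += pt.s[i]; s2 += sq(pt.s[i]); }
          double k = s2 > 0 ? ss / s2 : 0.0;
          double e = std::exp(pt.ls_bb) * norm_rand();
          double bprop = pt.b + e;
          double betaprop = pt.beta - e * k;
          double acc = 0.0;
          if (bprop > 0.0 && betaprop >= 0.0) {
            double ssr = ssr_with(pt, betaprop, bprop, pt.s);
            double d = -(ssr - pt.SSR) * inv2s2 -
                       0.5 * (sq((bprop - b_loc) / b_scale) -
                              sq((pt.b - b_loc) / b_scale)) -
                       0.5 * (sq((betaprop - G.beta_g) / sdb2) -
                              sq((pt.beta - G.beta_g) / sdb2));
            acc = d >= 0 ? 1.0 : std::exp(d);
            if (unif_rand() < acc) {
              pt.b = bprop; pt.beta = betaprop; pt.SSR = ssr;
            }
          }
          if (adapting) pt.ls_bb += gam * (acc - target);
        }
        // log sigma
        {
          double prop = pt.lsig + std::exp(pt.ls_lsig) * norm_rand();
          double sp = std::exp(prop);
          double d = -pt.N * (prop - pt.lsig) -
                     0.5 * pt.SSR * (1.0 / sq(sp) - 1.0 / sq(pt.sig)) -
                     0.5 * (sq(sp / ns) - sq(pt.sig / ns)) + (prop - pt.lsig);
          double acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) { pt.lsig = prop; pt.sig = sp; }
          if (adapting) pt.ls_lsig += gam * (acc - target);
          inv2s2 = 1.0 / (2.0 * sq(pt.sig));
        }
        // meal-time offsets: random-walk moves, interleaved with
        // prior-independence proposals so the chain can hop between
        // the separated modes a jittered meal time can induce
        if (est_off && pt.M > 0) for (int sweep = 0; sweep < 2; ++sweep) {
          double acc_sum = 0.0; int n_rw = 0;
          double step = std::exp(pt.ls_delta);
          double inv = 1.0 / (2.0 * sq(pt.alpha));
          for (int m = 0; m < pt.M; ++m) {
            bool indep = unif_rand() < 0.3;
            double prop = indep ? jit * norm_rand()
                                : pt.delta[m] + step * norm_rand();
            double acc = 0.0;
            if (std::fabs(prop) <= dmax) {
              double tau = pt.r[m] + prop;
              double *col = &pt.B[(size_t)m * pt.N];
              s_prop.resize(pt.N);
              col_prop.resize(pt.N);
              for (int i = 0; i < pt.N; ++i) {
                col_prop[i] = std::exp(-sq(pt.t[i] - tau) * inv);
                s_prop[i] = pt.s[i] + pt.c[m] * (col_prop[i] - col[i]);
              }
              double ssr = ssr_with(pt, pt.beta, pt.b, s_prop);
              // prior terms cancel against the independence proposal
              double d = -(ssr - pt.SSR) * inv2s2;
              if (!indep)
                d -= 0.5 * (sq(prop / jit) - sq(pt.delta[m] / jit));
              acc = d >= 0 ? 1.0 : std::exp(d);
              if (unif_rand() < acc) {
                pt.delta[m] = prop; pt.SSR = ssr;
                std::copy(s_prop.begin(), s_prop.end(), pt.s.begin());
                std::copy(col_prop.begin(), col_prop.end(), col);
              }
            }
            if (!indep) { acc_sum += acc; ++n_rw; }
          }
          if (adapting && n_rw > 0)
            pt.ls_delta += gam * (acc_sum / n_rw - target);
        }
      }

      // --- store draw ---
      if (it >= warmup) {
        int row = it - warmup, k = 0;
        draws(row, k++) = G.beta_g;
        draws(row, k++) = std::exp(G.lag);
        draws(row, k++) = std::exp(G.lsdb);
        draws(row, k++) = std::exp(G.lsda);
        for (int p = 0; p < P; ++p) {
          draws(row, k++) = pats[p].beta;
          draws(row, k++) = pats[p].alpha;
          draws(row, k++) = pats[p].b;
          draws(row, k++) = pats[p].sig;
          for (int m = 0; m < pats[p].M; ++m) draws(row, k++) = pats[p].delta[m];
        }
      }
      if (it % 256 == 0) Rcpp::checkUserInterrupt();
    }
    chains_out[ch] = draws;
  }
  return chains_out;
}
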