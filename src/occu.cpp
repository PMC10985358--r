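// Core numerics for the two-species dynamic carrion-occupancy model.
//
// Latent weekly joint state z in {1=U, 2=A, 3=R, 4=AR}; daily observed state
// y in {0=unobserved, 1=neither, 2=A only, 3=R only, 4=both}.  Each
// camera-winter is an independent hidden Markov chain over at most 7 weekly
// primary periods of 7 days; the likelihood marginalizes the latent states
// with the forward algorithm (weekly rescaling, log accumulation).
//
// Parameter vector layout (0-based), species s in {0=A, 1=R}:
//   fixed effects, 23 per species, species A first:
//     psi:  int, CLG, TFG, rodent, feeding                     [0..4]
//     gam:  int, CLG, TFG, rodent, feeding, comp,
//           comp:rodent, comp:feeding                          [5..12]
//     eps:  same 8 as gam                                      [13..20]
//     rho:  int, no-carrion                                    [21..22]
//   sigma[8]: (s, block) with block in {psi, gam, eps, rho}    [46..53]
//   year REs: u[s][block][t], t = 0..T-1                       [54..54+8T-1]

#include <Rcpp.h>
using namespace Rcpp;

static const int NFIX = 46;
static const int NSIG = 8;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline int sig_idx(int s, int b) { return NFIX + 4 * s + b; }
static inline int re_idx(int s, int b, int t, int T) {
  return NFIX + NSIG + (4 * s + b) * T + t;
}

struct Pack {
  int N, T, W, D;
  const int *obs;      // N x W x D, winter-major: obs[i*W*D + w*D + d]
  const int *carrion;  // same shape, 0/1
  const int *year;     // N, 1-based
  const double *X;     // N x 4 column-major (R matrix): CLG TFG rodent feeding
  int cond;            // 0 = departing-state conditioning, 1 = arriving
};

// Per-winter derived probabilities.
struct WinterProbs {
  double psi[2];
  double gam[2], gam_c[2];  // colonization, competitor absent / present
  double eps[2], eps_c[2];
  double rho1[2], rho0[2];  // detection with carrion present / absent
};

static void winter_probs(const Pack &pk, int i, const double *th,
                         WinterProbs &wp) {
  int t = pk.year[i] - 1;
  double x[4];
  for (int k = 0; k < 4; ++k) x[k] = pk.X[i + k * pk.N];
  for (int s = 0; s < 2; ++s) {
    int off = 23 * s;
    double lp_psi = th[off + 0];
    for (int k = 0; k < 4; ++k) lp_psi += th[off + 1 + k] * x[k];
    lp_psi += th[re_idx(s, 0, t, pk.T)];
    wp.psi[s] = invlogit(lp_psi);

    double lp_gam = th[off + 5];
    for (int k = 0; k < 4; ++k) lp_gam += th[off + 6 + k] * x[k];
    lp_gam += th[re_idx(s, 1, t, pk.T)];
    double comp_g = th[off + 10] + th[off + 11] * x[2] + th[off + 12] * x[3];
    wp.gam[s] = invlogit(lp_gam);
    wp.gam_c[s] = invlogit(lp_gam + comp_g);

    double lp_eps = th[off + 13];
    for (int k = 0; k < 4; ++k) lp_eps += th[off + 14 + k] * x[k];
    lp_eps += th[re_idx(s, 2, t, pk.T)];
    double comp_e = th[off + 18] + th[off + 19] * x[2] + th[off + 20] * x[3];
    wp.eps[s] = invlogit(lp_eps);
    wp.eps_c[s] = invlogit(lp_eps + comp_e);

    double lp_rho = th[off + 21] + th[re_idx(s, 3, t, pk.T)];
    wp.rho1[s] = invlogit(lp_rho);
    wp.rho0[s] = invlogit(lp_rho + th[off + 22]);
  }
}

// 4x4 row-stochastic weekly transition matrix, row-major Tm[from*4 + to].
static void transition_matrix(const WinterProbs &wp, int cond, double *Tm) {
  double gA = wp.gam[0], gAc = wp.gam_c[0], gR = wp.gam[1], gRc = wp.gam_c[1];
  double eA = wp.eps[0], eAc = wp.eps_c[0], eR = wp.eps[1], eRc = wp.eps_c[1];
  if (cond == 0) {
    // Condition on the competitor's state in the departing week.
    // Row U: neither present -> unconditional colonizations.
    Tm[0] = (1 - gA) * (1 - gR); Tm[1] = gA * (1 - gR);
    Tm[2] = (1 - gA) * gR;       Tm[3] = gA * gR;
    // Row A: A persists with 1-eps_A (R absent); R colonizes with gam_R|A.
    Tm[4] = eA * (1 - gRc);      Tm[5] = (1 - eA) * (1 - gRc);
    Tm[6] = eA * gRc;            Tm[7] = (1 - eA) * gRc;
    // Row R.
    Tm[8]  = (1 - gAc) * eR;     Tm[9]  = gAc * eR;
    Tm[10] = (1 - gAc) * (1 - eR); Tm[11] = gAc * (1 - eR);
    // Row AR: both persistences conditioned on competitor presence.
    Tm[12] = eAc * eRc;          Tm[13] = (1 - eAc) * eRc;
    Tm[14] = eAc * (1 - eRc);    Tm[15] = (1 - eAc) * (1 - eRc);
  } else {
    // Condition on the competitor's state in the arriving week; the cell
    // products no longer form a probability measure, so rows are renormalized.
    // pA[from R state][to A state], etc.
    for (int zf = 0; zf < 4; ++zf) {
      int af = (zf == 1 || zf == 3), rf = (zf == 2 || zf == 3);
      double rowsum = 0.0;
      for (int zt = 0; zt < 4; ++zt) {
        int at = (zt == 1 || zt == 3), rt = (zt == 2 || zt == 3);
        double pa = af ? (at ? 1 - (rt ? eAc : eA) : (rt ? eAc : eA))
                       : (at ? (rt ? gAc : gA) : 1 - (rt ? gAc : gA));
        double pr = rf ? (rt ? 1 - (at ? eRc : eR) : (at ? eRc : eR))
                       : (rt ? (at ? gRc : gR) : 1 - (at ? gRc : gR));
        Tm[zf * 4 + zt] = pa * pr;
        rowsum += pa * pr;
      }
      for (int zt = 0; zt < 4; ++zt) Tm[zf * 4 + zt] /= rowsum;
    }
  }
}

// Daily emission probability P(y | z) for one day.
static inline double emis(int z, int y, double rA, double rR) {
  if (y == 0) return 1.0;  // unobserved day
  // z is 0-based (0=U..3=AR); y is 1-based (1=neither..4=both)
  bool zA = (z == 1 || z == 3), zR = (z == 2 || z == 3);
  bool yA = (y == 2 || y == 4), yR = (y == 3 || y == 4);
  if ((yA && !zA) || (yR && !zR)) return 0.0;  // no false positives
  double p = 1.0;
  if (zA) p *= yA ? rA : (1.0 - rA);
  if (zR) p *= yR ? rR : (1.0 - rR);
  return p;
}

// Weekly emission vector e[z] = prod over observed days, and last week with
// any observation (1-based; 0 if none).
static void week_emissions(const Pack &pk, int i, const WinterProbs &wp,
                           double *E /* W x 4 */, int &lastw) {
  lastw = 0;
  for (int w = 0; w < pk.W; ++w) {
    double e0 = 1, e1 = 1, e2 = 1, e3 = 1;
    bool any = false;
    for (int d = 0; d < pk.D; ++d) {
      int y = pk.obs[(size_t)i * pk.W * pk.D + w * pk.D + d];
      if (y == 0) continue;
      any = true;
      int c = pk.carrion[(size_t)i * pk.W * pk.D + w * pk.D + d];
      double rA = c ? wp.rho1[0] : wp.rho0[0];
      double rR = c ? wp.rho1[1] : wp.rho0[1];
      e0 *= emis(0, y, rA, rR);
      e1 *= emis(1, y, rA, rR);
      e2 *= emis(2, y, rA, rR);
      e3 *= emis(3, y, rA, rR);
    }
    E[w * 4 + 0] = e0; E[w * 4 + 1] = e1; E[w * 4 + 2] = e2; E[w * 4 + 3] = e3;
    if (any) lastw = w + 1;
  }
}

// Forward log-likelihood for winter i.
static double winter_loglik(const Pack &pk, int i, const double *th) {
  WinterProbs wp;
  winter_probs(pk, i, th, wp);
  double Tm[16];
  transition_matrix(wp, pk.cond, Tm);
  double E[7 * 4];
  int lastw;
  week_emissions(pk, i, wp, E, lastw);
  if (lastw == 0) return 0.0;  // fully unobserved winter

  double a[4] = {(1 - wp.psi[0]) * (1 - wp.psi[1]),
                 wp.psi[0] * (1 - wp.psi[1]),
                 (1 - wp.psi[0]) * wp.psi[1],
                 wp.psi[0] * wp.psi[1]};
  double ll = 0.0;
  for (int w = 0; w < lastw; ++w) {
    if (w > 0) {
      double b[4] = {0, 0, 0, 0};
      for (int zf = 0; zf < 4; ++zf)
        for (int zt = 0; zt < 4; ++zt) b[zt] += a[zf] * Tm[zf * 4 + zt];
      for (int z = 0; z < 4; ++z) a[z] = b[z];
    }
    double s = 0.0;
    for (int z = 0; z < 4; ++z) { a[z] *= E[w * 4 + z]; s += a[z]; }
    if (s <= 0.0) return R_NegInf;
    for (int z = 0; z < 4; ++z) a[z] /= s;
    ll += std::log(s);
  }
  return ll;
}

static Pack make_pack(const IntegerVector &obs, const IntegerVector &carrion,
                      const IntegerVector &year, const NumericMatrix &X,
                      int T, int cond) {
  Pack pk;
  pk.N = X.nrow(); pk.T = T; pk.W = 7; pk.D = 7;
  pk.obs = INTEGER(obs); pk.carrion = INTEGER(carrion);
  pk.year = INTEGER(year); pk.X = REAL(X); pk.cond = cond;
  return pk;
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_loglik(IntegerVector obs, IntegerVector carrion,
                         IntegerVector year, NumericMatrix X, int n_years,
                         NumericVector theta, int cond) {
  Pack pk = make_pack(obs, carrion, year, X, n_years, cond);
  NumericVector out(pk.N);
  for (int i = 0; i < pk.N; ++i) out[i] = winter_loglik(pk, i, REAL(theta));
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_transition_matrix(NumericVector p, int cond) {
  // p = (gam_A, gam_A|comp, gam_R, gam_R|comp, eps_A, eps_A|comp,
  //      eps_R, eps_R|comp)
  WinterProbs wp;
  wp.gam[0] = p[0]; wp.gam_c[0] = p[1]; wp.gam[1] = p[2]; wp.gam_c[1] = p[3];
  wp.eps[0] = p[4]; wp.eps_c[0] = p[5]; wp.eps[1] = p[6]; wp.eps_c[1] = p[7];
  double Tm[16];
  transition_matrix(wp, cond, Tm);
  NumericMatrix out(4, 4);
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = Tm[r * 4 + c];
  return out;
}

// Conditional weekly latent-state marginals P(z_w | data) per winter
// (forward-backward), returned as N x 28 (weeks nested in states? no:
// column = (w-1)*4 + z). Weeks beyond the last observed week are propagated
// through the transition kernel (prediction).
// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_state_marginals(IntegerVector obs, IntegerVector carrion,
                                  IntegerVector year, NumericMatrix X,
                                  int n_years, NumericVector theta, int cond) {
  Pack pk = make_pack(obs, carrion, year, X, n_years, cond);
  NumericMatrix out(pk.N, 7 * 4);
  const double *th = REAL(theta);
  for (int i = 0; i < pk.N; ++i) {
    WinterProbs wp;
    winter_probs(pk, i, th, wp);
    double Tm[16];
    transition_matrix(wp, pk.cond, Tm);
    double E[7 * 4];
    int lastw;
    week_emissions(pk, i, wp, E, lastw);

    double A[7][4];  // scaled forward
    double a[4] = {(1 - wp.psi[0]) * (1 - wp.psi[1]),
                   wp.psi[0] * (1 - wp.psi[1]),
                   (1 - wp.psi[0]) * wp.psi[1],
                   wp.psi[0] * wp.psi[1]};
    for (int w = 0; w < 7; ++w) {
      if (w > 0) {
        double b[4] = {0, 0, 0, 0};
        for (int zf = 0; zf < 4; ++zf)
          for (int zt = 0; zt < 4; ++zt) b[zt] += a[zf] * Tm[zf * 4 + zt];
        for (int z = 0; z < 4; ++z) a[z] = b[z];
      }
      double s = 0.0;
      for (int z = 0; z < 4; ++z) { a[z] *= E[w * 4 + z]; s += a[z]; }
      if (s <= 0.0) s = 1.0;
      for (int z = 0; z < 4; ++z) { a[z] /= s; A[w][z] = a[z]; }
    }
    double bb[4] = {1, 1, 1, 1};
    for (int w = 6; w >= 0; --w) {
      double tot = 0.0, m[4];
      for (int z = 0; z < 4; ++z) { m[z] = A[w][z] * bb[z]; tot += m[z]; }
      for (int z = 0; z < 4; ++z) out(i, w * 4 + z) = m[z] / tot;
      if (w > 0) {
        double nb[4];
        double sc = 0.0;
        for (int zf = 0; zf < 4; ++zf) {
          double v = 0.0;
          for (int zt = 0; zt < 4; ++zt)
            v += Tm[zf * 4 + zt] * E[w * 4 + zt] * bb[zt];
          nb[zf] = v; sc += v;
        }
        for (int z = 0; z < 4; ++z) bb[z] = nb[z] / (sc / 4.0);
      }
    }
  }
  return out;
}

// Simulate latent chains and daily observations on a fixed design
// (observed-day mask and carrion flags taken from `obs` != 0 / `carrion`).
// Uses R's RNG. Returns list(z = N x 7 latent states, obs = like input).
// [[Rcpp::export(rng = false)]]
List cpp_simulate(IntegerVector obs, IntegerVector carrion, IntegerVector year,
                  NumericMatrix X, int n_years, NumericVector theta,
                  int cond) {
  Pack pk = make_pack(obs, carrion, year, X, n_years, cond);
  IntegerMatrix z(pk.N, 7);
  IntegerVector newobs(clone(obs));
  const double *th = REAL(theta);
  GetRNGstate();
  for (int i = 0; i < pk.N; ++i) {
    WinterProbs wp;
    winter_probs(pk, i, th, wp);
    double Tm[16];
    transition_matrix(wp, pk.cond, Tm);
    int zi = 0;
    bool zA = unif_rand() < wp.psi[0], zR = unif_rand() < wp.psi[1];
    zi = (zA ? 1 : 0) + (zR ? 2 : 0);
    for (int w = 0; w < 7; ++w) {
      if (w > 0) {
        double u = unif_rand(), cum = 0.0;
        int nz = 3;
        for (int zt = 0; zt < 4; ++zt) {
          cum += Tm[zi * 4 + zt];
          if (u < cum) { nz = zt; break; }
        }
        zi = nz;
      }
      z(i, w) = zi + 1;
      bool hasA = (zi == 1 || zi == 3), hasR = (zi == 2 || zi == 3);
      for (int d = 0; d < pk.D; ++d) {
        size_t idx = (size_t)i * pk.W * pk.D + w * pk.D + d;
        if (pk.obs[idx] == 0) continue;  // keep missingness pattern
        int c = pk.carrion[idx];
        bool dA = hasA && unif_rand() < (c ? wp.rho1[0] : wp.rho0[0]);
        bool dR = hasR && unif_rand() < (c ? wp.rho1[1] : wp.rho0[1]);
        newobs[idx] = 1 + (dA ? 1 : 0) + (dR ? 2 : 0);
      }
    }
  }
  PutRNGstate();
  return List::create(_["z"] = z, _["obs"] = newobs);
}

static inline double logis_lpdf(double x) {
  // Logistic(0,1) log density
  return -x - 2.0 * std::log1p(std::exp(-x));
}

// Full log prior (used for checking / R-side log_posterior).
// [[Rcpp::export(rng = false)]]
double cpp_logprior(NumericVector theta, int n_years, double sigma_upper) {
  const double *th = REAL(theta);
  double lp = 0.0;
  for (int j = 0; j < NFIX; ++j) lp += logis_lpdf(th[j]);
  for (int s = 0; s < 2; ++s)
    for (int b = 0; b < 4; ++b) {
      double sg = th[sig_idx(s, b)];
      if (sg < 0.0 || sg > sigma_upper) return R_NegInf;
      lp += -std::log(sigma_upper);
      for (int t = 0; t < n_years; ++t) {
        double u = th[re_idx(s, b, t, n_years)];
        lp += -0.5 * std::log(2.0 * M_PI) - std::log(sg) -
              u * u / (2.0 * sg * sg);
      }
    }
  return lp;
}

// Adaptive Metropolis-within-Gibbs (Roberts & Rosenthal 2009 scaling).
// Components listed in `free` (0-based) are updated; everything else is held
// fixed. Uses R's RNG; seed via set.seed() in R.
// [[Rcpp::export(rng = false)]]
List cpp_sampler(IntegerVector obs, IntegerVector carrion, IntegerVector year,
                 NumericMatrix X, int n_years, NumericVector theta0,
                 IntegerVector free, double sigma_upper, int n_adapt,
                 int n_iter, int thin, int cond, bool use_lik) {
  Pack pk = make_pack(obs, carrion, year, X, n_years, cond);
  int P = theta0.size(), nf = free.size(), T = n_years;
  std::vector<double> th(REAL(theta0), REAL(theta0) + P);
  std::vector<double> ls(nf, std::log(0.3)), acc(nf, 0.0), tries(nf, 0.0);
  std::vector<double> bacc(nf, 0.0), btry(nf, 0.0);

  // winters affected by each free component: -1 = all, -2 = none (sigma),
  // t >= 0 = winters of year t.
  std::vector<int> scope_of(nf);
  for (int j = 0; j < nf; ++j) {
    int idx = free[j];
    if (idx < NFIX) scope_of[j] = -1;
    else if (idx < NFIX + NSIG) scope_of[j] = -2;
    else scope_of[j] = (idx - NFIX - NSIG) % T;
  }
  std::vector<std::vector<int>> by_year(T);
  for (int i = 0; i < pk.N; ++i) by_year[pk.year[i] - 1].push_back(i);

  std::vector<double> cll(pk.N, 0.0);
  if (use_lik)
    for (int i = 0; i < pk.N; ++i) cll[i] = winter_loglik(pk, i, th.data());

  int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, P);
  int kept = 0, batch = 0;
  GetRNGstate();

  int total = n_adapt + n_iter;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < nf; ++j) {
      int idx = free[j];
      double cur = th[idx];
      double prop = cur + norm_rand() * std::exp(ls[j]);
      double dlp = 0.0;
      bool reject = false;

      if (idx < NFIX) {
        dlp += logis_lpdf(prop) - logis_lpdf(cur);
      } else if (idx < NFIX + NSIG) {
        if (prop <= 0.0 || prop > sigma_upper) reject = true;
        else {
          int k = idx - NFIX;  // (s*4 + b)
          double ssq = 0.0;
          for (int t = 0; t < T; ++t) {
            double u = th[NFIX + NSIG + k * T + t];
            ssq += u * u;
          }
          dlp += -T * (std::log(prop) - std::log(cur)) -
                 ssq / 2.0 * (1.0 / (prop * prop) - 1.0 / (cur * cur));
        }
      } else {
        int k = (idx - NFIX - NSIG) / T;  // combined (s*4 + b)
        double sg = th[NFIX + k];         // sigma for this (s, block)
        dlp += -(prop * prop - cur * cur) / (2.0 * sg * sg);
      }

      double newll_sum = 0.0, oldll_sum = 0.0;
      std::vector<std::pair<int, double>> updated;
      if (!reject && use_lik && scope_of[j] != -2) {
        th[idx] = prop;
        if (scope_of[j] == -1) {
          for (int i = 0; i < pk.N; ++i) {
            double nl = winter_loglik(pk, i, th.data());
            updated.push_back({i, nl});
            newll_sum += nl; oldll_sum += cll[i];
          }
        } else {
          for (int i : by_year[scope_of[j]]) {
            double nl = winter_loglik(pk, i, th.data());
            updated.push_back({i, nl});
            newll_sum += nl; oldll_sum += cll[i];
          }
        }
        th[idx] = cur;
      }

      double lr = dlp + newll_sum - oldll_sum;
      btry[j] += 1.0;
      if (!reject && (lr >= 0.0 || std::log(unif_rand()) < lr)) {
        th[idx] = prop;
        for (auto &pr : updated) cll[pr.first] = pr.second;
        bacc[j] += 1.0;
        if (it >= n_adapt) acc[j] += 1.0;
      }
      if (it >= n_adapt) tries[j] += 1.0;
    }

    // batch adaptation every 50 sweeps during the adaptation phase
    if (it < n_adapt && (it + 1) % 50 == 0) {
      ++batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < nf; ++j) {
        double rate = btry[j] > 0 ? bacc[j] / btry[j] : 0.0;
        ls[j] += (rate > 0.44 ? delta : -delta);
        bacc[j] = 0.0; btry[j] = 0.0;
      }
    }

    if (it >= n_adapt && ((it - n_adapt + 1) % thin == 0) && kept < n_keep) {
      for (int p = 0; p < P; ++p) draws(kept, p) = th[p];
      ++kept;
    }
  }

  PutRNGstate();
  NumericVector arate(nf);
  for (int j = 0; j < nf; ++j)
    arate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = arate,
                      _["log_step"] = NumericVector(ls.begin(), ls.end()));
}
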