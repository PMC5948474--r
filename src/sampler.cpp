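// Metropolis-within-Gibbs samplers for the five rater-effect IRT models.
//
// One single chain per fit. Scalar random-walk proposals per parameter
// (log-scale for positivity-constrained discriminations/spreads, order
// rejection inside threshold blocks), exact categorical Gibbs draws for the
// HRM's latent ideal ratings. Proposal scales adapt during burn-in only and
// are frozen afterwards so retained draws form a valid Markov chain.
// Identifiability-fixed parameters are never updated. Uses R's RNG so that
// set.seed() governs the whole fit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int KMAX = 15;

// ------------------------------------------------------------------ utils

static inline double l1pe(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double lse(const double* z, int K) {
  double m = z[0];
  for (int k = 1; k < K; ++k) if (z[k] > m) m = z[k];
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(z[k] - m);
  return m + std::log(s);
}

// log p(x | .) of a partial-credit family member: eta_m supplied per step
static inline double ll_cumlogit(const double* eta, int K, int x) {
  double z[KMAX];
  double c = 0.0;
  for (int k = 0; k < K; ++k) { c += eta[k]; z[k] = c; }
  return z[x - 1] - lse(z, K);
}

// log p(x) of a graded-response family member from decreasing boundary
// logits a[0..K-2]; differences taken in log space
static inline double ll_grm(const double* a, int K, int x) {
  if (x == 1) return -l1pe(a[0]);
  if (x == K) return -l1pe(-a[K - 2]);
  double hi = a[x - 2], lo = a[x - 1];
  double diff = hi - lo;
  if (diff < 1e-12) diff = 1e-12;
  return lo + std::log(std::expm1(diff)) - l1pe(hi) - l1pe(lo);
}

// log p(x | xi) of the HRM signal-detection stage
static inline double ll_sdt(int x, int xi, double sg, double ps, int K) {
  double z[KMAX];
  double inv = 1.0 / (2.0 * ps * ps);
  for (int c = 0; c < K; ++c) {
    double e = (c + 1) - (xi + sg);
    z[c] = -e * e * inv;
  }
  return z[x - 1] - lse(z, K);
}

struct Adapt {
  double s;
  int acc = 0, n = 0;
  explicit Adapt(double s0 = 0.5) : s(s0) {}
  void tick(bool a) { n++; if (a) acc++; }
  void maybe(bool adapting) {
    if (n >= 50) {
      if (adapting) {
        double r = (double)acc / n;
        s *= std::exp(0.8 * (r - 0.4));
        s = std::min(std::max(s, 1e-3), 10.0);
      }
      acc = 0; n = 0;
    }
  }
  double rate_total = 0; long n_total = 0;
  void record(bool a) { n_total++; if (a) rate_total += 1.0; }
  double rate() const { return n_total ? rate_total / n_total : NA_REAL; }
};

struct Obs {
  std::vector<int> i, j, r, x;
  int N, I, J, R, K;
  std::vector<std::vector<int>> by_j, by_i, by_r, by_ij, by_ir;
  Obs(IntegerVector oi, IntegerVector oj, IntegerVector orr, IntegerVector ox,
      int I_, int J_, int R_, int K_)
      : N(oi.size()), I(I_), J(J_), R(R_), K(K_) {
    i.resize(N); j.resize(N); r.resize(N); x.resize(N);
    by_j.resize(J); by_i.resize(I); by_r.resize(R);
    by_ij.resize((size_t)I * J); by_ir.resize((size_t)I * R);
    for (int n = 0; n < N; ++n) {
      i[n] = oi[n] - 1; j[n] = oj[n] - 1; r[n] = orr[n] - 1; x[n] = ox[n];
      by_j[j[n]].push_back(n);
      by_i[i[n]].push_back(n);
      by_r[r[n]].push_back(n);
      by_ij[(size_t)i[n] * J + j[n]].push_back(n);
      by_ir[(size_t)i[n] * R + r[n]].push_back(n);
    }
  }
};

struct Prior {
  double sd_theta, sd_loc, mu_la, sd_la, mu_lp, sd_lp, var_ord, cov_ord;
  std::vector<double> mu_ord;
  // quadratic form of the ordered-block multivariate normal prior
  double quad(const double* x, int m) const {
    double a = var_ord - cov_ord;
    double denom = a + cov_ord * m;
    double se = 0.0, s2 = 0.0;
    for (int k = 0; k < m; ++k) {
      double e = x[k] - mu_ord[k];
      se += e; s2 += e * e;
    }
    return (s2 - (cov_ord / denom) * se * se) / a;
  }
  double lp_ord(const double* x, int m) const { return -0.5 * quad(x, m); }
};

static Prior read_prior(List pr) {
  Prior p;
  p.sd_theta = as<double>(pr["sd_theta"]);
  p.sd_loc = as<double>(pr["sd_loc"]);
  p.mu_la = as<double>(pr["mu_logalpha"]);
  p.sd_la = as<double>(pr["sd_logalpha"]);
  p.mu_lp = as<double>(pr["mu_logpsi"]);
  p.sd_lp = as<double>(pr["sd_logpsi"]);
  p.var_ord = as<double>(pr["var_ord"]);
  p.cov_ord = as<double>(pr["cov_ord"]);
  NumericVector mo = pr["mu_ord"];
  p.mu_ord.assign(mo.begin(), mo.end());
  return p;
}

static inline double lp_norm(double x, double mu, double sd) {
  double e = (x - mu) / sd;
  return -0.5 * e * e;
}

// Joint location-shift move: theta and the task-location block share a
// likelihood-flat direction (theta + c, location + c) in models whose task
// locations carry no identifiability pin; a joint proposal along it mixes
// that direction at prior speed. The acceptance ratio is prior-only.
// Units without observations are left untouched (their parameters stay at
// the prior mean, and they contribute no likelihood either way).
static bool shift_move(std::vector<double>& th, std::vector<double>& loc,
                       const std::vector<std::vector<int>>& by_th,
                       const std::vector<std::vector<int>>& by_loc,
                       double extra_lp_delta, double scale, const Prior& pr) {
  double c = scale * norm_rand();
  double dlp = extra_lp_delta;
  for (size_t j = 0; j < th.size(); ++j)
    if (!by_th[j].empty())
      dlp += lp_norm(th[j] + c, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta);
  for (size_t i = 0; i < loc.size(); ++i)
    if (!by_loc[i].empty())
      dlp += lp_norm(loc[i] + c, 0, pr.sd_loc) - lp_norm(loc[i], 0, pr.sd_loc);
  if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
    for (size_t j = 0; j < th.size(); ++j) if (!by_th[j].empty()) th[j] += c;
    for (size_t i = 0; i < loc.size(); ++i) if (!by_loc[i].empty()) loc[i] += c;
    return true;
  }
  return false;
}

// Shared scaffolding: a scalar Metropolis update over a set of observations.
// `prop_ll(n)` must return the observation log-probability under the
// proposed state; on acceptance the cached per-observation values in `ll`
// are replaced.
template <typename F>
static bool mh_scalar(const std::vector<int>& idx, std::vector<double>& ll,
                      std::vector<double>& buf, double lprior_delta,
                      F prop_ll) {
  double dll = lprior_delta;
  buf.resize(idx.size());
  for (size_t t = 0; t < idx.size(); ++t) {
    int n = idx[t];
    buf[t] = prop_ll(n);
    dll += buf[t] - ll[n];
  }
  if (dll >= 0.0 || unif_rand() < std::exp(dll)) {
    for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
    return true;
  }
  return false;
}

struct Keeper {
  int S, s = 0;
  NumericMatrix pointwise;
  NumericVector loglik;
  std::map<std::string, NumericMatrix> blocks;
  Keeper(int S_, int N) : S(S_), pointwise(S_, N), loglik(S_) {}
  void add_block(const std::string& nm, int p) {
    blocks.emplace(nm, NumericMatrix(S, p));
  }
  void store(const std::string& nm, const double* v, int p) {
    NumericMatrix& m = blocks.at(nm);
    for (int c = 0; c < p; ++c) m(s, c) = v[c];
  }
  void store_pointwise(const std::vector<double>& lp) {
    double tot = 0.0;
    for (size_t n = 0; n < lp.size(); ++n) { pointwise(s, n) = lp[n]; tot += lp[n]; }
    loglik[s] = tot;
  }
  List samples() const {
    List out;
    for (auto& kv : blocks) out[kv.first] = kv.second;
    return out;
  }
};

// ------------------------------------------------------------------- MFRM

static List fit_mfrm(const Obs& o, const Prior& pr, int iters, int burn,
                     int thin) {
  int J = o.J, I = o.I, R = o.R, K = o.K;
  std::vector<double> th(J, 0.0), bi(I, 0.0), br(R, 0.0), d(K, 0.0);
  std::vector<double> ll(o.N), buf;
  auto obs_ll = [&](int n, double thv, double biv, double brv,
                    const double* dv) {
    double eta[KMAX];
    double base = thv - biv - brv;
    for (int k = 0; k < K; ++k) eta[k] = base - dv[k];
    return ll_cumlogit(eta, K, o.x[n]);
  };
  for (int n = 0; n < o.N; ++n)
    ll[n] = obs_ll(n, th[o.j[n]], bi[o.i[n]], br[o.r[n]], d.data());

  Adapt a_th(0.5), a_bi(0.3), a_br(0.3), a_d(0.15), a_sh(0.1);
  int S = (iters - burn) / thin;
  Keeper keep(S, o.N);
  keep.add_block("theta", J); keep.add_block("beta_task", I);
  keep.add_block("beta_rater", R); keep.add_block("d_cat", K);

  for (int it = 1; it <= iters; ++it) {
    bool adapting = it <= burn;
    for (int j = 0; j < J; ++j) {
      if (o.by_j[j].empty()) continue;
      double p = th[j] + a_th.s * norm_rand();
      bool acc = mh_scalar(o.by_j[j], ll, buf,
        lp_norm(p, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta),
        [&](int n) { return obs_ll(n, p, bi[o.i[n]], br[o.r[n]], d.data()); });
      if (acc) th[j] = p;
      a_th.tick(acc); if (!adapting) a_th.record(acc);
    }
    a_th.maybe(adapting);
    for (int i = 0; i < I; ++i) {
      if (o.by_i[i].empty()) continue;
      double p = bi[i] + a_bi.s * norm_rand();
      bool acc = mh_scalar(o.by_i[i], ll, buf,
        lp_norm(p, 0, pr.sd_loc) - lp_norm(bi[i], 0, pr.sd_loc),
        [&](int n) { return obs_ll(n, th[o.j[n]], p, br[o.r[n]], d.data()); });
      if (acc) bi[i] = p;
      a_bi.tick(acc); if (!adapting) a_bi.record(acc);
    }
    a_bi.maybe(adapting);
    for (int r = 1; r < R; ++r) { // rater 1 severity fixed at 0
      if (o.by_r[r].empty()) continue;
      double p = br[r] + a_br.s * norm_rand();
      bool acc = mh_scalar(o.by_r[r], ll, buf,
        lp_norm(p, 0, pr.sd_loc) - lp_norm(br[r], 0, pr.sd_loc),
        [&](int n) { return obs_ll(n, th[o.j[n]], bi[o.i[n]], p, d.data()); });
      if (acc) br[r] = p;
      a_br.tick(acc); if (!adapting) a_br.record(acc);
    }
    a_br.maybe(adapting);
    // free thresholds d[1..K-2]; d[K-1] set by the sum-to-zero constraint
    std::vector<int> all_n(o.N); // d changes touch every observation
    for (int m = 1; m <= K - 2; ++m) {
      double e = a_d.s * norm_rand();
      double dprop[KMAX];
      std::copy(d.begin(), d.end(), dprop);
      dprop[m] += e; dprop[K - 1] -= e;
      double lpd = lp_norm(dprop[m], 0, pr.sd_loc) - lp_norm(d[m], 0, pr.sd_loc);
      double dll = lpd;
      buf.resize(o.N);
      for (int n = 0; n < o.N; ++n) {
        buf[n] = obs_ll(n, th[o.j[n]], bi[o.i[n]], br[o.r[n]], dprop);
        dll += buf[n] - ll[n];
      }
      bool acc = (dll >= 0.0 || unif_rand() < std::exp(dll));
      if (acc) { std::copy(dprop, dprop + K, d.begin()); ll.assign(buf.begin(), buf.end()); }
      a_d.tick(acc); if (!adapting) a_d.record(acc);
    }
    a_d.maybe(adapting);
    {
      bool acc = shift_move(th, bi, o.by_j, o.by_i, 0.0, a_sh.s, pr);
      a_sh.tick(acc); if (!adapting) a_sh.record(acc);
      a_sh.maybe(adapting);
    }
    {
      // severity trade: beta_r + c (r >= 2) with beta_i - c changes the
      // likelihood only through the reference rater's observations — a
      // softly identified direction that scalar updates traverse slowly
      double c = a_sh.s * norm_rand();
      double dlp = 0.0;
      for (int r = 1; r < R; ++r)
        if (!o.by_r[r].empty())
          dlp += lp_norm(br[r] + c, 0, pr.sd_loc) - lp_norm(br[r], 0, pr.sd_loc);
      for (int i = 0; i < I; ++i)
        if (!o.by_i[i].empty())
          dlp += lp_norm(bi[i] - c, 0, pr.sd_loc) - lp_norm(bi[i], 0, pr.sd_loc);
      const std::vector<int>& idx = o.by_r[0];
      buf.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int n = idx[t];
        buf[t] = obs_ll(n, th[o.j[n]], bi[o.i[n]] - c, 0.0, d.data());
        dlp += buf[t] - ll[n];
      }
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        for (int r = 1; r < R; ++r) if (!o.by_r[r].empty()) br[r] += c;
        for (int i = 0; i < I; ++i) if (!o.by_i[i].empty()) bi[i] -= c;
        for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
      }
    }

    if (it > burn && (it - burn) % thin == 0) {
      keep.store("theta", th.data(), J);
      keep.store("beta_task", bi.data(), I);
      keep.store("beta_rater", br.data(), R);
      keep.store("d_cat", d.data(), K);
      keep.store_pointwise(ll);
      keep.s++;
    }
  }
  return List::create(_["samples"] = keep.samples(),
                      _["pointwise"] = keep.pointwise,
                      _["loglik"] = keep.loglik,
                      _["accept"] = List::create(
                        _["theta"] = a_th.rate(), _["beta_task"] = a_bi.rate(),
                        _["beta_rater"] = a_br.rate(), _["d_cat"] = a_d.rate()));
}

// --------------------------------------------------------------- Patz1999

static List fit_patz(const Obs& o, const Prior& pr, int iters, int burn,
                     int thin) {
  int J = o.J, I = o.I, R = o.R, K = o.K;
  std::vector<double> th(J, 0.0), la(I, pr.mu_la);
  std::vector<double> beta((size_t)I * K, 0.0), rho((size_t)I * R, 0.0);
  std::vector<double> ll(o.N), buf;
  auto obs_ll = [&](int n, double thv, double lav, const double* be,
                    double rh) {
    double eta[KMAX];
    double al = std::exp(lav);
    for (int k = 0; k < K; ++k) eta[k] = al * (thv - be[k] - rh);
    return ll_cumlogit(eta, K, o.x[n]);
  };
  auto cur_ll = [&](int n) {
    return obs_ll(n, th[o.j[n]], la[o.i[n]], &beta[(size_t)o.i[n] * K],
                  rho[(size_t)o.i[n] * R + o.r[n]]);
  };
  for (int n = 0; n < o.N; ++n) ll[n] = cur_ll(n);

  Adapt a_th(0.5), a_la(0.2), a_be(0.2), a_rh(0.3);
  int S = (iters - burn) / thin;
  Keeper keep(S, o.N);
  keep.add_block("theta", J); keep.add_block("alpha", I);
  keep.add_block("beta_step", I * K); keep.add_block("rho", I * R);

  for (int it = 1; it <= iters; ++it) {
    bool adapting = it <= burn;
    for (int j = 0; j < J; ++j) {
      if (o.by_j[j].empty()) continue;
      double p = th[j] + a_th.s * norm_rand();
      bool acc = mh_scalar(o.by_j[j], ll, buf,
        lp_norm(p, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta),
        [&](int n) { return obs_ll(n, p, la[o.i[n]], &beta[(size_t)o.i[n] * K],
                                   rho[(size_t)o.i[n] * R + o.r[n]]); });
      if (acc) th[j] = p;
      a_th.tick(acc); if (!adapting) a_th.record(acc);
    }
    a_th.maybe(adapting);
    for (int i = 0; i < I; ++i) {
      if (o.by_i[i].empty()) continue;
      double p = la[i] + a_la.s * norm_rand();
      bool acc = mh_scalar(o.by_i[i], ll, buf,
        lp_norm(p, pr.mu_la, pr.sd_la) - lp_norm(la[i], pr.mu_la, pr.sd_la),
        [&](int n) { return obs_ll(n, th[o.j[n]], p, &beta[(size_t)i * K],
                                   rho[(size_t)i * R + o.r[n]]); });
      if (acc) la[i] = p;
      a_la.tick(acc); if (!adapting) a_la.record(acc);
      for (int m = 1; m < K; ++m) { // beta_step[i][0] fixed at 0
        double bp[KMAX];
        std::copy(&beta[(size_t)i * K], &beta[(size_t)i * K] + K, bp);
        double pb = bp[m] + a_be.s * norm_rand();
        double lpd = lp_norm(pb, 0, pr.sd_loc) - lp_norm(bp[m], 0, pr.sd_loc);
        bp[m] = pb;
        bool accb = mh_scalar(o.by_i[i], ll, buf, lpd,
          [&](int n) { return obs_ll(n, th[o.j[n]], la[i], bp,
                                     rho[(size_t)i * R + o.r[n]]); });
        if (accb) beta[(size_t)i * K + m] = pb;
        a_be.tick(accb); if (!adapting) a_be.record(accb);
      }
      for (int r = 1; r < R; ++r) { // reference rater fixed per task
        const std::vector<int>& idx = o.by_ir[(size_t)i * R + r];
        if (idx.empty()) continue;
        double cur = rho[(size_t)i * R + r];
        double p2 = cur + a_rh.s * norm_rand();
        bool accr = mh_scalar(idx, ll, buf,
          lp_norm(p2, 0, pr.sd_loc) - lp_norm(cur, 0, pr.sd_loc),
          [&](int n) { return obs_ll(n, th[o.j[n]], la[i],
                                     &beta[(size_t)i * K], p2); });
        if (accr) rho[(size_t)i * R + r] = p2;
        a_rh.tick(accr); if (!adapting) a_rh.record(accr);
      }
    }
    a_la.maybe(adapting); a_be.maybe(adapting); a_rh.maybe(adapting);
    {
      // location trade: theta + c with every non-reference severity + c;
      // only the reference raters' observations see a likelihood change
      double c = 0.1 * norm_rand();
      double dlp = 0.0;
      for (int j = 0; j < J; ++j)
        if (!o.by_j[j].empty())
          dlp += lp_norm(th[j] + c, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta);
      for (int i = 0; i < I; ++i)
        for (int r = 1; r < R; ++r)
          if (!o.by_ir[(size_t)i * R + r].empty())
            dlp += lp_norm(rho[(size_t)i * R + r] + c, 0, pr.sd_loc) -
                   lp_norm(rho[(size_t)i * R + r], 0, pr.sd_loc);
      const std::vector<int>& idx = o.by_r[0];
      buf.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int n = idx[t];
        buf[t] = obs_ll(n, th[o.j[n]] + c, la[o.i[n]],
                        &beta[(size_t)o.i[n] * K], 0.0);
        dlp += buf[t] - ll[n];
      }
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        for (int j = 0; j < J; ++j) if (!o.by_j[j].empty()) th[j] += c;
        for (int i = 0; i < I; ++i)
          for (int r = 1; r < R; ++r)
            if (!o.by_ir[(size_t)i * R + r].empty())
              rho[(size_t)i * R + r] += c;
        for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
      }
    }

    if (it > burn && (it - burn) % thin == 0) {
      keep.store("theta", th.data(), J);
      std::vector<double> al(I);
      for (int i = 0; i < I; ++i) al[i] = std::exp(la[i]);
      keep.store("alpha", al.data(), I);
      keep.store("beta_step", beta.data(), I * K);
      keep.store("rho", rho.data(), I * R);
      keep.store_pointwise(ll);
      keep.s++;
    }
  }
  return List::create(_["samples"] = keep.samples(),
                      _["pointwise"] = keep.pointwise,
                      _["loglik"] = keep.loglik,
                      _["accept"] = List::create(
                        _["theta"] = a_th.rate(), _["alpha"] = a_la.rate(),
                        _["beta_step"] = a_be.rate(), _["rho"] = a_rh.rate()));
}

// --------------------------------------------------------------- Ueno2008

static List fit_ueno(const Obs& o, const Prior& pr, int iters, int burn,
                     int thin) {
  int J = o.J, I = o.I, R = o.R, K = o.K, M = K - 1;
  std::vector<double> th(J, 0.0), la(I, pr.mu_la), b(I, 0.0);
  std::vector<double> eps((size_t)R * M);
  for (int r = 0; r < R; ++r)
    for (int m = 0; m < M; ++m) eps[(size_t)r * M + m] = pr.mu_ord[m];
  eps[0] = -1.0; // identifiability: first rater's first threshold
  for (int m = 1; m < M; ++m)
    if (eps[m] <= eps[m - 1]) eps[m] = eps[m - 1] + 0.25;

  std::vector<double> ll(o.N), buf;
  auto obs_ll = [&](int n, double thv, double lav, double bv,
                    const double* er) {
    double a[KMAX];
    double al = std::exp(lav);
    for (int m = 0; m < M; ++m) a[m] = al * (thv - bv - er[m]);
    return ll_grm(a, K, o.x[n]);
  };
  auto cur_ll = [&](int n) {
    return obs_ll(n, th[o.j[n]], la[o.i[n]], b[o.i[n]],
                  &eps[(size_t)o.r[n] * M]);
  };
  for (int n = 0; n < o.N; ++n) ll[n] = cur_ll(n);

  Adapt a_th(0.5), a_la(0.2), a_b(0.3), a_ep(0.15), a_sh(0.1);
  int S = (iters - burn) / thin;
  Keeper keep(S, o.N);
  keep.add_block("theta", J); keep.add_block("alpha", I);
  keep.add_block("b_task", I); keep.add_block("eps", R * M);

  for (int it = 1; it <= iters; ++it) {
    bool adapting = it <= burn;
    for (int j = 0; j < J; ++j) {
      if (o.by_j[j].empty()) continue;
      double p = th[j] + a_th.s * norm_rand();
      bool acc = mh_scalar(o.by_j[j], ll, buf,
        lp_norm(p, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta),
        [&](int n) { return obs_ll(n, p, la[o.i[n]], b[o.i[n]],
                                   &eps[(size_t)o.r[n] * M]); });
      if (acc) th[j] = p;
      a_th.tick(acc); if (!adapting) a_th.record(acc);
    }
    a_th.maybe(adapting);
    for (int i = 0; i < I; ++i) {
      if (o.by_i[i].empty()) continue;
      double p = la[i] + a_la.s * norm_rand();
      bool acc = mh_scalar(o.by_i[i], ll, buf,
        lp_norm(p, pr.mu_la, pr.sd_la) - lp_norm(la[i], pr.mu_la, pr.sd_la),
        [&](int n) { return obs_ll(n, th[o.j[n]], p, b[o.i[n]],
                                   &eps[(size_t)o.r[n] * M]); });
      if (acc) la[i] = p;
      a_la.tick(acc); if (!adapting) a_la.record(acc);
      double pb = b[i] + a_b.s * norm_rand();
      bool accb = mh_scalar(o.by_i[i], ll, buf,
        lp_norm(pb, 0, pr.sd_loc) - lp_norm(b[i], 0, pr.sd_loc),
        [&](int n) { return obs_ll(n, th[o.j[n]], la[i], pb,
                                   &eps[(size_t)o.r[n] * M]); });
      if (accb) b[i] = pb;
      a_b.tick(accb); if (!adapting) a_b.record(accb);
    }
    a_la.maybe(adapting); a_b.maybe(adapting);
    for (int r = 0; r < R; ++r) {
      if (o.by_r[r].empty()) continue;
      double* er = &eps[(size_t)r * M];
      for (int m = 0; m < M; ++m) {
        if (r == 0 && m == 0) continue; // eps[1][1] = -1.0 fixed
        double p = er[m] + a_ep.s * norm_rand();
        // reject proposals violating the within-rater order
        if ((m > 0 && p <= er[m - 1]) || (m < M - 1 && p >= er[m + 1])) {
          a_ep.tick(false); if (!adapting) a_ep.record(false);
          continue;
        }
        double ep[KMAX];
        std::copy(er, er + M, ep);
        ep[m] = p;
        double lpd = pr.lp_ord(ep, M) - pr.lp_ord(er, M);
        bool acc = mh_scalar(o.by_r[r], ll, buf, lpd,
          [&](int n) { return obs_ll(n, th[o.j[n]], la[o.i[n]], b[o.i[n]], ep); });
        if (acc) er[m] = p;
        a_ep.tick(acc); if (!adapting) a_ep.record(acc);
      }
    }
    a_ep.maybe(adapting);
    {
      bool acc = shift_move(th, b, o.by_j, o.by_i, 0.0, a_sh.s, pr);
      a_sh.tick(acc); if (!adapting) a_sh.record(acc);
      a_sh.maybe(adapting);
    }
    {
      // severity trade: every non-reference rater's thresholds + c with
      // b_i - c; the likelihood moves only through rater 1's observations
      double c = a_sh.s * norm_rand();
      double dlp = 0.0;
      double ep[KMAX];
      for (int r = 1; r < R; ++r) {
        if (o.by_r[r].empty()) continue;
        const double* er = &eps[(size_t)r * M];
        for (int m = 0; m < M; ++m) ep[m] = er[m] + c;
        dlp += pr.lp_ord(ep, M) - pr.lp_ord(er, M);
      }
      for (int i = 0; i < I; ++i)
        if (!o.by_i[i].empty())
          dlp += lp_norm(b[i] - c, 0, pr.sd_loc) - lp_norm(b[i], 0, pr.sd_loc);
      const std::vector<int>& idx = o.by_r[0];
      buf.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int n = idx[t];
        buf[t] = obs_ll(n, th[o.j[n]], la[o.i[n]], b[o.i[n]] - c, &eps[0]);
        dlp += buf[t] - ll[n];
      }
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        for (int r = 1; r < R; ++r) {
          if (o.by_r[r].empty()) continue;
          for (int m = 0; m < M; ++m) eps[(size_t)r * M + m] += c;
        }
        for (int i = 0; i < I; ++i) if (!o.by_i[i].empty()) b[i] -= c;
        for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
      }
    }

    if (it > burn && (it - burn) % thin == 0) {
      keep.store("theta", th.data(), J);
      std::vector<double> al(I);
      for (int i = 0; i < I; ++i) al[i] = std::exp(la[i]);
      keep.store("alpha", al.data(), I);
      keep.store("b_task", b.data(), I);
      keep.store("eps", eps.data(), R * M);
      keep.store_pointwise(ll);
      keep.s++;
    }
  }
  return List::create(_["samples"] = keep.samples(),
                      _["pointwise"] = keep.pointwise,
                      _["loglik"] = keep.loglik,
                      _["accept"] = List::create(
                        _["theta"] = a_th.rate(), _["alpha"] = a_la.rate(),
                        _["b_task"] = a_b.rate(), _["eps"] = a_ep.rate()));
}

// --------------------------------------------------------------- Uto2016

static List fit_uto(const Obs& o, const Prior& pr, int iters, int burn,
                    int thin) {
  int J = o.J, I = o.I, R = o.R, K = o.K, M = K - 1;
  std::vector<double> th(J, 0.0), lai(I, pr.mu_la), lar(R, 0.0), er(R, 0.0);
  std::vector<double> b((size_t)I * M);
  for (int i = 0; i < I; ++i)
    for (int m = 0; m < M; ++m) b[(size_t)i * M + m] = pr.mu_ord[m];

  std::vector<double> ll(o.N), buf;
  auto obs_ll = [&](int n, double thv, double laiv, double larv,
                    const double* bi, double erv) {
    double a[KMAX];
    double al = std::exp(laiv) * std::exp(larv);
    for (int m = 0; m < M; ++m) a[m] = al * (thv - bi[m] - erv);
    return ll_grm(a, K, o.x[n]);
  };
  auto cur_ll = [&](int n) {
    return obs_ll(n, th[o.j[n]], lai[o.i[n]], lar[o.r[n]],
                  &b[(size_t)o.i[n] * M], er[o.r[n]]);
  };
  for (int n = 0; n < o.N; ++n) ll[n] = cur_ll(n);

  Adapt a_th(0.5), a_la(0.2), a_lar(0.2), a_b(0.15), a_er(0.3), a_sh(0.1);
  int S = (iters - burn) / thin;
  Keeper keep(S, o.N);
  keep.add_block("theta", J); keep.add_block("alpha_task", I);
  keep.add_block("alpha_rater", R); keep.add_block("b_cat", I * M);
  keep.add_block("eps_rater", R);

  for (int it = 1; it <= iters; ++it) {
    bool adapting = it <= burn;
    for (int j = 0; j < J; ++j) {
      if (o.by_j[j].empty()) continue;
      double p = th[j] + a_th.s * norm_rand();
      bool acc = mh_scalar(o.by_j[j], ll, buf,
        lp_norm(p, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta),
        [&](int n) { return obs_ll(n, p, lai[o.i[n]], lar[o.r[n]],
                                   &b[(size_t)o.i[n] * M], er[o.r[n]]); });
      if (acc) th[j] = p;
      a_th.tick(acc); if (!adapting) a_th.record(acc);
    }
    a_th.maybe(adapting);
    for (int i = 0; i < I; ++i) {
      if (o.by_i[i].empty()) continue;
      double p = lai[i] + a_la.s * norm_rand();
      bool acc = mh_scalar(o.by_i[i], ll, buf,
        lp_norm(p, pr.mu_la, pr.sd_la) - lp_norm(lai[i], pr.mu_la, pr.sd_la),
        [&](int n) { return obs_ll(n, th[o.j[n]], p, lar[o.r[n]],
                                   &b[(size_t)i * M], er[o.r[n]]); });
      if (acc) lai[i] = p;
      a_la.tick(acc); if (!adapting) a_la.record(acc);
      double* bi = &b[(size_t)i * M];
      for (int m = 0; m < M; ++m) {
        double p2 = bi[m] + a_b.s * norm_rand();
        if ((m > 0 && p2 <= bi[m - 1]) || (m < M - 1 && p2 >= bi[m + 1])) {
          a_b.tick(false); if (!adapting) a_b.record(false);
          continue;
        }
        double bp[KMAX];
        std::copy(bi, bi + M, bp);
        bp[m] = p2;
        double lpd = pr.lp_ord(bp, M) - pr.lp_ord(bi, M);
        bool accb = mh_scalar(o.by_i[i], ll, buf, lpd,
          [&](int n) { return obs_ll(n, th[o.j[n]], lai[i], lar[o.r[n]],
                                     bp, er[o.r[n]]); });
        if (accb) bi[m] = p2;
        a_b.tick(accb); if (!adapting) a_b.record(accb);
      }
    }
    a_la.maybe(adapting); a_b.maybe(adapting);
    for (int r = 1; r < R; ++r) { // rater 1: alpha fixed 1, eps fixed 0
      if (o.by_r[r].empty()) continue;
      double p = lar[r] + a_lar.s * norm_rand();
      bool acc = mh_scalar(o.by_r[r], ll, buf,
        lp_norm(p, 0, pr.sd_lp) - lp_norm(lar[r], 0, pr.sd_lp),
        [&](int n) { return obs_ll(n, th[o.j[n]], lai[o.i[n]], p,
                                   &b[(size_t)o.i[n] * M], er[r]); });
      if (acc) lar[r] = p;
      a_lar.tick(acc); if (!adapting) a_lar.record(acc);
      double p2 = er[r] + a_er.s * norm_rand();
      bool acce = mh_scalar(o.by_r[r], ll, buf,
        lp_norm(p2, 0, pr.sd_loc) - lp_norm(er[r], 0, pr.sd_loc),
        [&](int n) { return obs_ll(n, th[o.j[n]], lai[o.i[n]], lar[r],
                                   &b[(size_t)o.i[n] * M], p2); });
      if (acce) er[r] = p2;
      a_er.tick(acce); if (!adapting) a_er.record(acce);
    }
    a_lar.maybe(adapting); a_er.maybe(adapting);
    {
      // consistency trade: alpha_r * e^u (r >= 2) with alpha_i * e^{-u};
      // only the reference rater's observations see a change. Without this
      // move a degraded reference rater pins the whole discrimination scale
      double u = a_sh.s * norm_rand();
      double dlp = 0.0;
      for (int r = 1; r < R; ++r)
        if (!o.by_r[r].empty())
          dlp += lp_norm(lar[r] + u, 0, pr.sd_lp) - lp_norm(lar[r], 0, pr.sd_lp);
      for (int i = 0; i < I; ++i)
        if (!o.by_i[i].empty())
          dlp += lp_norm(lai[i] - u, pr.mu_la, pr.sd_la) -
                 lp_norm(lai[i], pr.mu_la, pr.sd_la);
      const std::vector<int>& idx = o.by_r[0];
      buf.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int n = idx[t];
        buf[t] = obs_ll(n, th[o.j[n]], lai[o.i[n]] - u, lar[0],
                        &b[(size_t)o.i[n] * M], er[0]);
        dlp += buf[t] - ll[n];
      }
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        for (int r = 1; r < R; ++r) if (!o.by_r[r].empty()) lar[r] += u;
        for (int i = 0; i < I; ++i) if (!o.by_i[i].empty()) lai[i] -= u;
        for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
      }
    }
    {
      // severity trade: eps_r + c (r >= 2) with every task threshold - c;
      // again only rater 1's observations change
      double c = a_sh.s * norm_rand();
      double dlp = 0.0;
      double bp[KMAX];
      for (int r = 1; r < R; ++r)
        if (!o.by_r[r].empty())
          dlp += lp_norm(er[r] + c, 0, pr.sd_loc) - lp_norm(er[r], 0, pr.sd_loc);
      for (int i = 0; i < I; ++i) {
        if (o.by_i[i].empty()) continue;
        const double* bi = &b[(size_t)i * M];
        for (int m = 0; m < M; ++m) bp[m] = bi[m] - c;
        dlp += pr.lp_ord(bp, M) - pr.lp_ord(bi, M);
      }
      const std::vector<int>& idx = o.by_r[0];
      buf.resize(idx.size());
      for (size_t t = 0; t < idx.size(); ++t) {
        int n = idx[t];
        for (int m = 0; m < M; ++m)
          bp[m] = b[(size_t)o.i[n] * M + m] - c;
        buf[t] = obs_ll(n, th[o.j[n]], lai[o.i[n]], lar[0], bp, er[0]);
        dlp += buf[t] - ll[n];
      }
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        for (int r = 1; r < R; ++r) if (!o.by_r[r].empty()) er[r] += c;
        for (int i = 0; i < I; ++i) {
          if (o.by_i[i].empty()) continue;
          for (int m = 0; m < M; ++m) b[(size_t)i * M + m] -= c;
        }
        for (size_t t = 0; t < idx.size(); ++t) ll[idx[t]] = buf[t];
      }
    }
    {
      // shifting every ordered task block changes its multivariate normal
      // prior; theta gets its usual normal ratio inside shift_move
      double c = a_sh.s * norm_rand();
      double dlp = 0.0;
      double bp[KMAX];
      for (int i = 0; i < I; ++i) {
        if (o.by_i[i].empty()) continue;
        const double* bi = &b[(size_t)i * M];
        for (int m = 0; m < M; ++m) bp[m] = bi[m] + c;
        dlp += pr.lp_ord(bp, M) - pr.lp_ord(bi, M);
      }
      for (int j = 0; j < J; ++j)
        if (!o.by_j[j].empty())
          dlp += lp_norm(th[j] + c, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta);
      bool acc = (dlp >= 0.0 || unif_rand() < std::exp(dlp));
      if (acc) {
        for (int j = 0; j < J; ++j) if (!o.by_j[j].empty()) th[j] += c;
        for (int i = 0; i < I; ++i) {
          if (o.by_i[i].empty()) continue;
          for (int m = 0; m < M; ++m) b[(size_t)i * M + m] += c;
        }
      }
      a_sh.tick(acc); if (!adapting) a_sh.record(acc);
      a_sh.maybe(adapting);
    }

    if (it > burn && (it - burn) % thin == 0) {
      keep.store("theta", th.data(), J);
      std::vector<double> al(I), ar(R);
      for (int i = 0; i < I; ++i) al[i] = std::exp(lai[i]);
      for (int r = 0; r < R; ++r) ar[r] = std::exp(lar[r]);
      keep.store("alpha_task", al.data(), I);
      keep.store("alpha_rater", ar.data(), R);
      keep.store("b_cat", b.data(), I * M);
      keep.store("eps_rater", er.data(), R);
      keep.store_pointwise(ll);
      keep.s++;
    }
  }
  return List::create(_["samples"] = keep.samples(),
                      _["pointwise"] = keep.pointwise,
                      _["loglik"] = keep.loglik,
                      _["accept"] = List::create(
                        _["theta"] = a_th.rate(), _["alpha_task"] = a_la.rate(),
                        _["alpha_rater"] = a_lar.rate(), _["b_cat"] = a_b.rate(),
                        _["eps_rater"] = a_er.rate()));
}

// ------------------------------------------------------------------- HRM

static List fit_hrm(const Obs& o, const Prior& pr, int iters, int burn,
                    int thin, IntegerVector xi_init) {
  int J = o.J, I = o.I, R = o.R, K = o.K;
  std::vector<double> th(J, 0.0), bi(I, 0.0), d((size_t)I * K, 0.0);
  std::vector<double> sg(R, 0.0), lp(R, 0.0); // lp = log psi
  std::vector<int> xi(xi_init.begin(), xi_init.end()); // I*J, column i-major
  std::vector<double> ll(o.N), buf; // observed-stage log-probs given xi
  std::vector<double> llxi((size_t)I * J); // stage-1 log p(xi | theta)

  auto pcm_ll = [&](int i, double thv, double biv, const double* dv, int k) {
    double eta[KMAX];
    double base = thv - biv;
    for (int m = 0; m < K; ++m) eta[m] = base - dv[m];
    return ll_cumlogit(eta, K, k);
  };
  auto sdt_ll = [&](int n, int k, double sgv, double lpv) {
    return ll_sdt(o.x[n], k, sgv, std::exp(lpv), K);
  };
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      llxi[(size_t)i * J + j] =
        pcm_ll(i, th[j], bi[i], &d[(size_t)i * K], xi[(size_t)i * J + j]);
  for (int n = 0; n < o.N; ++n)
    ll[n] = sdt_ll(n, xi[(size_t)o.i[n] * J + o.j[n]], sg[o.r[n]], lp[o.r[n]]);

  Adapt a_th(0.5), a_bi(0.3), a_d(0.2), a_sg(0.2), a_lp(0.2), a_sh(0.1);
  int S = (iters - burn) / thin;
  Keeper keep(S, o.N);
  keep.add_block("theta", J); keep.add_block("beta_task", I);
  keep.add_block("d_step", I * K); keep.add_block("xi", I * J);
  keep.add_block("sigma", R); keep.add_block("psi", R);

  for (int it = 1; it <= iters; ++it) {
    bool adapting = it <= burn;
    // exact Gibbs draw of each latent ideal rating
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < J; ++j) {
        const std::vector<int>& idx = o.by_ij[(size_t)i * J + j];
        double w[KMAX];
        for (int k = 1; k <= K; ++k) {
          double wk = pcm_ll(i, th[j], bi[i], &d[(size_t)i * K], k);
          for (int n : idx) wk += sdt_ll(n, k, sg[o.r[n]], lp[o.r[n]]);
          w[k - 1] = wk;
        }
        double tot = lse(w, K), u = unif_rand(), c = 0.0;
        int knew = K;
        for (int k = 0; k < K; ++k) {
          c += std::exp(w[k] - tot);
          if (u <= c) { knew = k + 1; break; }
        }
        xi[(size_t)i * J + j] = knew;
        llxi[(size_t)i * J + j] = pcm_ll(i, th[j], bi[i], &d[(size_t)i * K], knew);
        for (int n : idx) ll[n] = sdt_ll(n, knew, sg[o.r[n]], lp[o.r[n]]);
      }
    }
    // theta: enters only through the stage-1 PCM of each task's ideal rating
    for (int j = 0; j < J; ++j) {
      double p = th[j] + a_th.s * norm_rand();
      double dll = lp_norm(p, 0, pr.sd_theta) - lp_norm(th[j], 0, pr.sd_theta);
      buf.resize(I);
      for (int i = 0; i < I; ++i) {
        buf[i] = pcm_ll(i, p, bi[i], &d[(size_t)i * K], xi[(size_t)i * J + j]);
        dll += buf[i] - llxi[(size_t)i * J + j];
      }
      bool acc = (dll >= 0.0 || unif_rand() < std::exp(dll));
      if (acc) {
        th[j] = p;
        for (int i = 0; i < I; ++i) llxi[(size_t)i * J + j] = buf[i];
      }
      a_th.tick(acc); if (!adapting) a_th.record(acc);
    }
    a_th.maybe(adapting);
    // task parameters of the stage-1 PCM
    for (int i = 0; i < I; ++i) {
      double p = bi[i] + a_bi.s * norm_rand();
      double dll = lp_norm(p, 0, pr.sd_loc) - lp_norm(bi[i], 0, pr.sd_loc);
      buf.resize(J);
      for (int j = 0; j < J; ++j) {
        buf[j] = pcm_ll(i, th[j], p, &d[(size_t)i * K], xi[(size_t)i * J + j]);
        dll += buf[j] - llxi[(size_t)i * J + j];
      }
      bool acc = (dll >= 0.0 || unif_rand() < std::exp(dll));
      if (acc) {
        bi[i] = p;
        for (int j = 0; j < J; ++j) llxi[(size_t)i * J + j] = buf[j];
      }
      a_bi.tick(acc); if (!adapting) a_bi.record(acc);
      for (int m = 1; m <= K - 2; ++m) {
        double e = a_d.s * norm_rand();
        double dp[KMAX];
        std::copy(&d[(size_t)i * K], &d[(size_t)i * K] + K, dp);
        dp[m] += e; dp[K - 1] -= e;
        double dll2 = lp_norm(dp[m], 0, pr.sd_loc) -
                      lp_norm(d[(size_t)i * K + m], 0, pr.sd_loc);
        buf.resize(J);
        for (int j = 0; j < J; ++j) {
          buf[j] = pcm_ll(i, th[j], bi[i], dp, xi[(size_t)i * J + j]);
          dll2 += buf[j] - llxi[(size_t)i * J + j];
        }
        bool accd = (dll2 >= 0.0 || unif_rand() < std::exp(dll2));
        if (accd) {
          std::copy(dp, dp + K, &d[(size_t)i * K]);
          for (int j = 0; j < J; ++j) llxi[(size_t)i * J + j] = buf[j];
        }
        a_d.tick(accd); if (!adapting) a_d.record(accd);
      }
    }
    a_bi.maybe(adapting); a_d.maybe(adapting);
    // rater severity and spread of the signal-detection stage
    for (int r = 0; r < R; ++r) {
      if (o.by_r[r].empty()) continue;
      double p = sg[r] + a_sg.s * norm_rand();
      bool acc = mh_scalar(o.by_r[r], ll, buf,
        lp_norm(p, 0, pr.sd_loc) - lp_norm(sg[r], 0, pr.sd_loc),
        [&](int n) { return sdt_ll(n, xi[(size_t)o.i[n] * J + o.j[n]], p, lp[r]); });
      if (acc) sg[r] = p;
      a_sg.tick(acc); if (!adapting) a_sg.record(acc);
      double p2 = lp[r] + a_lp.s * norm_rand();
      bool acc2 = mh_scalar(o.by_r[r], ll, buf,
        lp_norm(p2, pr.mu_lp, pr.sd_lp) - lp_norm(lp[r], pr.mu_lp, pr.sd_lp),
        [&](int n) { return sdt_ll(n, xi[(size_t)o.i[n] * J + o.j[n]], sg[r], p2); });
      if (acc2) lp[r] = p2;
      a_lp.tick(acc2); if (!adapting) a_lp.record(acc2);
    }
    a_sg.maybe(adapting); a_lp.maybe(adapting);
    {
      // the stage-1 PCM depends on theta and beta_task only through their
      // difference, and the observed stage involves neither; every
      // (task, examinee) pair carries a latent ideal rating, so the shift
      // covers all units (stage-1 terms stay exactly invariant)
      double c = a_sh.s * norm_rand();
      double dlp = 0.0;
      for (double t : th) dlp += lp_norm(t + c, 0, pr.sd_theta) - lp_norm(t, 0, pr.sd_theta);
      for (double v : bi) dlp += lp_norm(v + c, 0, pr.sd_loc) - lp_norm(v, 0, pr.sd_loc);
      bool acc = (dlp >= 0.0 || unif_rand() < std::exp(dlp));
      if (acc) {
        for (double& t : th) t += c;
        for (double& v : bi) v += c;
      }
      a_sh.tick(acc); if (!adapting) a_sh.record(acc);
      a_sh.maybe(adapting);
    }

    if (it > burn && (it - burn) % thin == 0) {
      keep.store("theta", th.data(), J);
      keep.store("beta_task", bi.data(), I);
      keep.store("d_step", d.data(), I * K);
      std::vector<double> xid(xi.begin(), xi.end());
      keep.store("xi", xid.data(), I * J);
      keep.store("sigma", sg.data(), R);
      std::vector<double> ps(R);
      for (int r = 0; r < R; ++r) ps[r] = std::exp(lp[r]);
      keep.store("psi", ps.data(), R);
      // pointwise log-probabilities conditional on the current ideal
      // ratings: the ideal ratings are counted as model parameters by the
      // criteria's parameter-count accounting, so the criteria condition on
      // them rather than marginalizing
      keep.store_pointwise(ll);
      keep.s++;
    }
  }
  return List::create(_["samples"] = keep.samples(),
                      _["pointwise"] = keep.pointwise,
                      _["loglik"] = keep.loglik,
                      _["accept"] = List::create(
                        _["theta"] = a_th.rate(), _["beta_task"] = a_bi.rate(),
                        _["d_step"] = a_d.rate(), _["sigma"] = a_sg.rate(),
                        _["psi"] = a_lp.rate()));
}

// -------------------------------------------------------------- dispatch

// [[Rcpp::export]]
List cpp_fit_model(std::string model, IntegerVector oi, IntegerVector oj,
                   IntegerVector orr, IntegerVector ox, int I, int J, int R,
                   int K, int iters, int burn, int thin, List prior,
                   IntegerVector xi_init) {
  if (K > KMAX) stop("K too large for the compiled sampler");
  Obs o(oi, oj, orr, ox, I, J, R, K);
  Prior pr = read_prior(prior);
  if ((int)pr.mu_ord.size() != K - 1) stop("mu_ord must have length K-1");
  if (model == "mfrm") return fit_mfrm(o, pr, iters, burn, thin);
  if (model == "patz1999") return fit_patz(o, pr, iters, burn, thin);
  if (model == "ueno2008") return fit_ueno(o, pr, iters, burn, thin);
  if (model == "uto2016") return fit_uto(o, pr, iters, burn, thin);
  if (model == "hrm") return fit_hrm(o, pr, iters, burn, thin, xi_init);
  stop("unknown model id");
}
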