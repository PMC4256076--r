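// Two-state Gaussian-emission HMM on per-time-point sufficient statistics,
// plus the likelihood-ratio scan machinery. Emissions within a time point
// are iid, so each time point enters the forward-backward recursion as one
// block summarised by (n, sum, sum of squares); the cost per EM iteration is
// O(T) regardless of the number of strain pairs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659;

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log-likelihood of a block of n iid N(mu, sg^2) draws with sum s1, sumsq s2
static inline double block_ll(double n, double s1, double s2,
                              double mu, double sg) {
  return -0.5 * n * (LOG2PI + 2.0 * std::log(sg)) -
         (s2 - 2.0 * mu * s1 + n * mu * mu) / (2.0 * sg * sg);
}

struct FitRes {
  double mu[2], sg[2];
  std::vector<int> path;
  double ll_joint, ll_marg;
  int iter;
  bool conv;
  std::vector<double> trace;
};

// Baum-Welch with fixed transition probability (the penalty) and fixed
// initial state probability; only the Gaussian emission parameters are
// re-estimated. After convergence the state path is Viterbi-decoded and the
// emission parameters are refit in closed form given that path, so the
// reported joint log-likelihood is the maximised sequence-plus-emission
// objective (comparable with exhaustive enumeration over state sequences).
static FitRes fit_stats_core(const std::vector<double>& n,
                             const std::vector<double>& s1,
                             const std::vector<double>& s2,
                             double lambda, double pi0, double tol, int maxit,
                             double sfloor, bool have_init, const double* imu,
                             const double* isg, bool want_trace) {
  int T = (int)n.size();
  FitRes r;
  r.path.assign(T, 0);
  double N = 0, S1 = 0, S2 = 0;
  for (int t = 0; t < T; ++t) { N += n[t]; S1 += s1[t]; S2 += s2[t]; }
  double m = S1 / N;
  double v = S2 / N - m * m;
  if (v < 0) v = 0;
  double sd = std::sqrt(v);
  if (sd < sfloor) sd = sfloor;
  double mu[2], sg[2];
  if (have_init) {
    mu[0] = imu[0]; mu[1] = imu[1];
    sg[0] = std::max(isg[0], sfloor); sg[1] = std::max(isg[1], sfloor);
  } else {
    // low-effect-like start: shared pooled spread, distinct means
    mu[0] = m - 0.5 * sd; mu[1] = m + 0.5 * sd;
    sg[0] = sd; sg[1] = sd;
  }
  double lstay = std::log1p(-lambda), lsw = std::log(lambda);
  double lpi[2] = {std::log(pi0), std::log1p(-pi0)};
  std::vector<double> la(2 * T), lb(2 * T), le(2 * T), g0(T);
  double prev = R_NegInf;
  r.conv = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < 2; ++k)
        le[2 * t + k] = block_ll(n[t], s1[t], s2[t], mu[k], sg[k]);
    la[0] = lpi[0] + le[0];
    la[1] = lpi[1] + le[1];
    for (int t = 1; t < T; ++t) {
      la[2 * t] = le[2 * t] +
        lse2(la[2 * (t - 1)] + lstay, la[2 * (t - 1) + 1] + lsw);
      la[2 * t + 1] = le[2 * t + 1] +
        lse2(la[2 * (t - 1)] + lsw, la[2 * (t - 1) + 1] + lstay);
    }
    double ll = lse2(la[2 * (T - 1)], la[2 * (T - 1) + 1]);
    if (want_trace) r.trace.push_back(ll);
    if (it > 1 && ll - prev < tol) { r.conv = true; prev = ll; break; }
    prev = ll;
    lb[2 * (T - 1)] = 0.0;
    lb[2 * (T - 1) + 1] = 0.0;
    for (int t = T - 2; t >= 0; --t) {
      lb[2 * t] = lse2(lstay + le[2 * (t + 1)] + lb[2 * (t + 1)],
                       lsw + le[2 * (t + 1) + 1] + lb[2 * (t + 1) + 1]);
      lb[2 * t + 1] = lse2(lsw + le[2 * (t + 1)] + lb[2 * (t + 1)],
                           lstay + le[2 * (t + 1) + 1] + lb[2 * (t + 1) + 1]);
    }
    double W[2] = {0, 0}, M1[2] = {0, 0};
    for (int t = 0; t < T; ++t) {
      double l0 = la[2 * t] + lb[2 * t], l1 = la[2 * t + 1] + lb[2 * t + 1];
      double gm = 1.0 / (1.0 + std::exp(l1 - l0));
      g0[t] = gm;
      W[0] += gm * n[t];
      W[1] += (1 - gm) * n[t];
      M1[0] += gm * s1[t];
      M1[1] += (1 - gm) * s1[t];
    }
    double nmu[2];
    for (int k = 0; k < 2; ++k) nmu[k] = W[k] > 0 ? M1[k] / W[k] : mu[k];
    double V[2] = {0, 0};
    for (int t = 0; t < T; ++t) {
      double gm = g0[t];
      V[0] += gm * (s2[t] - 2 * nmu[0] * s1[t] + n[t] * nmu[0] * nmu[0]);
      V[1] += (1 - gm) *
              (s2[t] - 2 * nmu[1] * s1[t] + n[t] * nmu[1] * nmu[1]);
    }
    for (int k = 0; k < 2; ++k) {
      mu[k] = nmu[k];
      double s = W[k] > 0 ? std::sqrt(std::max(V[k] / W[k], 0.0)) : sg[k];
      sg[k] = s < sfloor ? sfloor : s;
    }
  }
  r.iter = it > maxit ? maxit : it;
  r.ll_marg = prev;
  // Viterbi decode at the converged parameters
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < 2; ++k)
      le[2 * t + k] = block_ll(n[t], s1[t], s2[t], mu[k], sg[k]);
  std::vector<double> d(2 * T);
  std::vector<int> bp(2 * T, 0);
  d[0] = lpi[0] + le[0];
  d[1] = lpi[1] + le[1];
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < 2; ++k) {
      double from0 = d[2 * (t - 1)] + (k == 0 ? lstay : lsw);
      double from1 = d[2 * (t - 1) + 1] + (k == 1 ? lstay : lsw);
      if (from1 > from0) { d[2 * t + k] = le[2 * t + k] + from1; bp[2 * t + k] = 1; }
      else { d[2 * t + k] = le[2 * t + k] + from0; bp[2 * t + k] = 0; }
    }
  }
  int s = d[2 * (T - 1) + 1] > d[2 * (T - 1)] ? 1 : 0;
  for (int t = T - 1; t >= 0; --t) {
    r.path[t] = s;
    if (t > 0) s = bp[2 * t + s];
  }
  // closed-form refit of the Gaussian parameters given the decoded path
  double Nk[2] = {0, 0}, A1[2] = {0, 0}, A2[2] = {0, 0};
  for (int t = 0; t < T; ++t) {
    int k = r.path[t];
    Nk[k] += n[t]; A1[k] += s1[t]; A2[k] += s2[t];
  }
  for (int k = 0; k < 2; ++k) {
    if (Nk[k] > 0) {
      double mk = A1[k] / Nk[k];
      double vk = A2[k] / Nk[k] - mk * mk;
      mu[k] = mk;
      sg[k] = std::max(std::sqrt(std::max(vk, 0.0)), sfloor);
    }
  }
  double seq = lpi[r.path[0]];
  for (int t = 1; t < T; ++t) seq += (r.path[t] == r.path[t - 1]) ? lstay : lsw;
  double em = 0;
  for (int t = 0; t < T; ++t)
    em += block_ll(n[t], s1[t], s2[t], mu[r.path[t]], sg[r.path[t]]);
  r.ll_joint = seq + em;
  r.mu[0] = mu[0]; r.mu[1] = mu[1];
  r.sg[0] = sg[0]; r.sg[1] = sg[1];
  return r;
}

static List fit_to_list(const FitRes& f) {
  return List::create(
      _["mu"] = NumericVector::create(f.mu[0], f.mu[1]),
      _["sigma"] = NumericVector::create(f.sg[0], f.sg[1]),
      _["path"] = IntegerVector(f.path.begin(), f.path.end()),
      _["log_likelihood"] = f.ll_joint,
      _["marginal_log_likelihood"] = f.ll_marg,
      _["n_iter"] = f.iter, _["converged"] = f.conv,
      _["trace"] = NumericVector(f.trace.begin(), f.trace.end()));
}

// [[Rcpp::export]]
List cpp_fit_stats(NumericVector n, NumericVector s1, NumericVector s2,
                   double lambda, double pi0, double tol, int maxit,
                   double sfloor,
                   Nullable<NumericVector> init_mu = R_NilValue,
                   Nullable<NumericVector> init_sigma = R_NilValue) {
  std::vector<double> vn(n.begin(), n.end()), v1(s1.begin(), s1.end()),
      v2(s2.begin(), s2.end());
  bool have_init = init_mu.isNotNull();
  double imu[2] = {0, 0}, isg[2] = {1, 1};
  if (have_init) {
    NumericVector a(init_mu), b(init_sigma);
    imu[0] = a[0]; imu[1] = a[1]; isg[0] = b[0]; isg[1] = b[1];
  }
  FitRes f = fit_stats_core(vn, v1, v2, lambda, pi0, tol, maxit, sfloor,
                            have_init, imu, isg, true);
  return fit_to_list(f);
}

// Per-time-point sufficient statistics of the cross-allele (D) and
// same-allele (B) difference samples, computed after within-(time, allele)
// variance stabilisation to sd 1 (means preserved). g codes allele A as 1,
// allele B as 0; NA expression entries are treated as unobserved.
struct TPStats {
  std::vector<double> Dn, Ds1, Ds2, Bn, Bs1, Bs2, nA, nB;
  std::vector<int> retained;
};

static void effect_stats_core(const NumericMatrix& Y, const int* g,
                              TPStats& out, int min_per_group) {
  int S = Y.nrow(), T = Y.ncol();
  out.Dn.assign(T, 0); out.Ds1.assign(T, 0); out.Ds2.assign(T, 0);
  out.Bn.assign(T, 0); out.Bs1.assign(T, 0); out.Bs2.assign(T, 0);
  out.nA.assign(T, 0); out.nB.assign(T, 0);
  out.retained.assign(T, 0);
  std::vector<double> a, b;
  a.reserve(S); b.reserve(S);
  for (int t = 0; t < T; ++t) {
    a.clear(); b.clear();
    for (int i = 0; i < S; ++i) {
      double y = Y(i, t);
      if (ISNAN(y)) continue;
      if (g[i] == 1) a.push_back(y);
      else if (g[i] == 0) b.push_back(y);
    }
    int na = (int)a.size(), nb = (int)b.size();
    out.nA[t] = na; out.nB[t] = nb;
    if (na < min_per_group || nb < min_per_group) continue;
    out.retained[t] = 1;
    // stabilise each allele group: x -> m + (x - m)/sd  (sample sd)
    for (int grp = 0; grp < 2; ++grp) {
      std::vector<double>& x = grp == 0 ? a : b;
      int nn = (int)x.size();
      double sm = 0;
      for (int i = 0; i < nn; ++i) sm += x[i];
      double mn = sm / nn, ss = 0;
      for (int i = 0; i < nn; ++i) ss += (x[i] - mn) * (x[i] - mn);
      double sdv = std::sqrt(ss / (nn - 1));
      if (sdv > 0)
        for (int i = 0; i < nn; ++i) x[i] = mn + (x[i] - mn) / sdv;
    }
    double Sa = 0, SSa = 0, Sb = 0, SSb = 0, wa = 0, wb = 0;
    for (int i = 0; i < na; ++i) {
      Sa += a[i]; SSa += a[i] * a[i];
      wa += (na + 1.0 - 2.0 * (i + 1)) * a[i];  // signed within-pair sums, i<j
    }
    for (int i = 0; i < nb; ++i) {
      Sb += b[i]; SSb += b[i] * b[i];
      wb += (nb + 1.0 - 2.0 * (i + 1)) * b[i];
    }
    out.Dn[t] = (double)na * nb;
    out.Ds1[t] = nb * Sa - na * Sb;
    out.Ds2[t] = nb * SSa + na * SSb - 2.0 * Sa * Sb;
    out.Bn[t] = 0.5 * na * (na - 1) + 0.5 * nb * (nb - 1);
    out.Bs1[t] = wa + wb;
    out.Bs2[t] = (na * SSa - Sa * Sa) + (nb * SSb - Sb * Sb);
  }
}

// [[Rcpp::export]]
List cpp_effect_stats(NumericMatrix Y, IntegerVector g, int min_per_group) {
  TPStats st;
  effect_stats_core(Y, INTEGER(g), st, min_per_group);
  return List::create(
      _["retained"] = IntegerVector(st.retained.begin(), st.retained.end()),
      _["n_A"] = NumericVector(st.nA.begin(), st.nA.end()),
      _["n_B"] = NumericVector(st.nB.begin(), st.nB.end()),
      _["D_n"] = NumericVector(st.Dn.begin(), st.Dn.end()),
      _["D_s1"] = NumericVector(st.Ds1.begin(), st.Ds1.end()),
      _["D_s2"] = NumericVector(st.Ds2.begin(), st.Ds2.end()),
      _["B_n"] = NumericVector(st.Bn.begin(), st.Bn.end()),
      _["B_s1"] = NumericVector(st.Bs1.begin(), st.Bs1.end()),
      _["B_s2"] = NumericVector(st.Bs2.begin(), st.Bs2.end()));
}

// DyVER score for one variant: fit D and B separately and pooled (per-time
// concatenation) over the retained time points; score is the log-likelihood
// ratio. Returns NA when fewer than two time points are retained.
static double score_core(const NumericMatrix& Y, const int* g, double lambda,
                         double pi0, double tol, int maxit, double sfloor,
                         int min_per_group, FitRes* dfit,
                         std::vector<int>* retained_out) {
  TPStats st;
  effect_stats_core(Y, g, st, min_per_group);
  std::vector<double> dn, d1, d2, bn, b1, b2, pn, p1, p2;
  int T = (int)st.retained.size();
  for (int t = 0; t < T; ++t) {
    if (!st.retained[t]) continue;
    dn.push_back(st.Dn[t]); d1.push_back(st.Ds1[t]); d2.push_back(st.Ds2[t]);
    bn.push_back(st.Bn[t]); b1.push_back(st.Bs1[t]); b2.push_back(st.Bs2[t]);
    pn.push_back(st.Dn[t] + st.Bn[t]);
    p1.push_back(st.Ds1[t] + st.Bs1[t]);
    p2.push_back(st.Ds2[t] + st.Bs2[t]);
  }
  if ((int)dn.size() < 2) return NA_REAL;
  double dummy_mu[2], dummy_sg[2];
  FitRes fd = fit_stats_core(dn, d1, d2, lambda, pi0, tol, maxit, sfloor,
                             false, dummy_mu, dummy_sg, false);
  FitRes fb = fit_stats_core(bn, b1, b2, lambda, pi0, tol, maxit, sfloor,
                             false, dummy_mu, dummy_sg, false);
  FitRes fp = fit_stats_core(pn, p1, p2, lambda, pi0, tol, maxit, sfloor,
                             false, dummy_mu, dummy_sg, false);
  if (dfit) *dfit = fd;
  if (retained_out) *retained_out = st.retained;
  return fd.ll_joint + fb.ll_joint - fp.ll_joint;
}

// Scan all variants for one gene. perm_mode: 0 = no permutations,
// 1 = permutation p for the top-scoring variant only, 2 = shared
// permutations across all variants (per-variant counts plus the familywise
// max-score count). Permutations use R's RNG.
// [[Rcpp::export]]
List cpp_scan_gene(NumericMatrix Y, IntegerMatrix G, double lambda,
                   double pi0, int n_perm, int perm_mode, double tol,
                   int maxit, double sfloor, int min_per_group) {
  int S = Y.nrow(), K = G.ncol();
  NumericVector score(K, NA_REAL);
  std::vector<int> gv(S);
  int best = -1;
  double best_score = R_NegInf;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < S; ++i) gv[i] = G(i, k);
    double sc = score_core(Y, gv.data(), lambda, pi0, tol, maxit, sfloor,
                           min_per_group, nullptr, nullptr);
    score[k] = sc;
    if (!ISNAN(sc) && sc > best_score) { best_score = sc; best = k; }
  }
  if (best < 0)
    return List::create(_["score"] = score, _["best"] = NA_INTEGER);
  for (int i = 0; i < S; ++i) gv[i] = G(i, best);
  FitRes bf;
  std::vector<int> retained;
  score_core(Y, gv.data(), lambda, pi0, tol, maxit, sfloor, min_per_group,
             &bf, &retained);
  List out = List::create(
      _["score"] = score, _["best"] = best + 1,
      _["best_fit"] = fit_to_list(bf),
      _["retained"] = IntegerVector(retained.begin(), retained.end()));
  if (perm_mode == 1 && n_perm > 0) {
    int cnt = 0;
    IntegerVector idx = seq_len(S);
    for (int r = 0; r < n_perm; ++r) {
      IntegerVector pidx = Rcpp::sample(idx, S, false);
      std::vector<int> gp(S);
      for (int i = 0; i < S; ++i) gp[i] = G(pidx[i] - 1, best);
      double sc = score_core(Y, gp.data(), lambda, pi0, tol, maxit, sfloor,
                             min_per_group, nullptr, nullptr);
      if (!ISNAN(sc) && sc >= best_score) ++cnt;
    }
    out["perm_count"] = cnt;
    out["n_perm"] = n_perm;
  } else if (perm_mode == 2 && n_perm > 0) {
    IntegerVector counts(K, 0);
    int max_cnt = 0;
    IntegerVector idx = seq_len(S);
    std::vector<int> gp(S);
    for (int r = 0; r < n_perm; ++r) {
      IntegerVector pidx = Rcpp::sample(idx, S, false);
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        if (ISNAN(score[k])) continue;
        for (int i = 0; i < S; ++i) gp[i] = G(pidx[i] - 1, k);
        double sc = score_core(Y, gp.data(), lambda, pi0, tol, maxit, sfloor,
                               min_per_group, nullptr, nullptr);
        if (ISNAN(sc)) continue;
        if (sc >= score[k]) counts[k] = counts[k] + 1;
        if (sc > mx) mx = sc;
      }
      if (mx >= best_score) ++max_cnt;
    }
    out["perm_counts"] = counts;
    out["perm_count"] = counts[best];
    out["max_count"] = max_cnt;
    out["n_perm"] = n_perm;
  }
  return out;
}
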