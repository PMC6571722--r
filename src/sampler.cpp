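// Monte Carlo core: SAMC / frozen-DoS production / fixed-T Metropolis sampling
// of a single flexible-semiflexible multiblock copolymer chain, plus the
// uniform shell-volume chain-growth reference sampler and per-conformation
// observables.  All randomness comes from R's RNG (unif_rand), so runs are
// pure functions of the R seed.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double TWOPI = 6.2831853071795864769;

struct Model {
  int N;
  std::vector<int> type;    // 1 = S, 0 = F
  std::vector<char> angok;  // angle center c (0-based, 1..N-2): all-S triplet
  double sigma2, lmin2, lmax2, rcut2, lmin3, lmax3;
  double cos_lo, cos_hi;    // cos(theta_max) .. cos(theta_min)
  double step;              // local-move half width
  int kmax;                 // max regrow length
  int eps[2][2];            // raw integer contact energies, [ti][tj]
  bool phantom;             // no hard sphere, no contacts
  int envcap;               // |Env_raw| upper bound
  int nstmax;
};

static Model build_model(const List& m) {
  Model M;
  M.N = as<int>(m["N"]);
  IntegerVector tp = m["types"];
  M.type.assign(tp.begin(), tp.end());
  double sigma = as<double>(m["sigma"]);
  double lmin = as<double>(m["l_min"]), lmax = as<double>(m["l_max"]);
  double rcut = as<double>(m["R_cut"]);
  M.sigma2 = sigma * sigma;
  M.lmin2 = lmin * lmin; M.lmax2 = lmax * lmax;
  M.lmin3 = lmin * lmin * lmin; M.lmax3 = lmax * lmax * lmax;
  M.rcut2 = rcut * rcut;
  M.cos_lo = std::cos(as<double>(m["theta_max"]) * M_PI / 180.0);
  M.cos_hi = std::cos(as<double>(m["theta_min"]) * M_PI / 180.0);
  M.step = as<double>(m["move_delta"]);
  M.kmax = as<int>(m["k_max"]);
  IntegerVector er = m["eps_raw"];  // ss, ff, sf
  M.eps[1][1] = er[0]; M.eps[0][0] = er[1];
  M.eps[0][1] = M.eps[1][0] = er[2];
  M.phantom = as<bool>(m["phantom"]);
  M.angok.assign(M.N, 0);
  M.nstmax = 0;
  for (int c = 1; c <= M.N - 2; ++c) {
    M.angok[c] = (M.type[c - 1] == 1 && M.type[c] == 1 && M.type[c + 1] == 1);
    if (M.angok[c]) M.nstmax++;
  }
  int maxabs = 0;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b) maxabs = std::max(maxabs, std::abs(M.eps[a][b]));
  long npair = (long)(M.N - 1) * (M.N - 2) / 2;  // non-bonded pairs
  M.envcap = M.phantom ? 0 : (int)(maxabs * npair);
  return M;
}

static inline double pdist2(const double* p, int i, int j) {
  double dx = p[3 * i] - p[3 * j];
  double dy = p[3 * i + 1] - p[3 * j + 1];
  double dz = p[3 * i + 2] - p[3 * j + 2];
  return dx * dx + dy * dy + dz * dz;
}

static inline bool ang_fav(const double* p, const Model& M, int c) {
  double ax = p[3 * (c - 1)] - p[3 * c], ay = p[3 * (c - 1) + 1] - p[3 * c + 1],
         az = p[3 * (c - 1) + 2] - p[3 * c + 2];
  double bx = p[3 * (c + 1)] - p[3 * c], by = p[3 * (c + 1) + 1] - p[3 * c + 1],
         bz = p[3 * (c + 1) + 2] - p[3 * c + 2];
  double dot = ax * bx + ay * by + az * bz;
  double nn = (ax * ax + ay * ay + az * az) * (bx * bx + by * by + bz * bz);
  double cth = dot / std::sqrt(nn);
  return cth >= M.cos_lo && cth <= M.cos_hi;
}

static void full_counts(const double* p, const Model& M, int& envraw, int& nst,
                        int& nss, int& nff, int& nsf) {
  envraw = 0; nst = 0; nss = nff = nsf = 0;
  if (!M.phantom) {
    for (int i = 0; i < M.N; ++i)
      for (int j = i + 2; j < M.N; ++j)
        if (pdist2(p, i, j) <= M.rcut2) {
          int ti = M.type[i], tj = M.type[j];
          envraw += M.eps[ti][tj];
          if (ti && tj) nss++;
          else if (!ti && !tj) nff++;
          else nsf++;
        }
  }
  for (int c = 1; c <= M.N - 2; ++c)
    if (M.angok[c] && ang_fav(p, M, c)) nst++;
}

// 0 = valid, otherwise 1-based index of first offending bead/pair start
static int full_validate(const double* p, const Model& M, int& kind) {
  for (int i = 0; i < M.N - 1; ++i) {
    double dd = pdist2(p, i, i + 1);
    if (dd < M.lmin2 || dd > M.lmax2) { kind = 1; return i + 1; }
  }
  if (!M.phantom)
    for (int i = 0; i < M.N; ++i)
      for (int j = i + 2; j < M.N; ++j)
        if (pdist2(p, i, j) < M.sigma2) { kind = 2; return i + 1; }
  kind = 0;
  return 0;
}

// bond vector uniform w.r.t. volume on the shell l_min <= |v| <= l_max
static inline void shell_vec(const Model& M, double* v) {
  double u = unif_rand();
  double r = std::cbrt(M.lmin3 + u * (M.lmax3 - M.lmin3));
  double z = 2.0 * unif_rand() - 1.0;
  double phi = TWOPI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  v[0] = r * s * std::cos(phi);
  v[1] = r * s * std::sin(phi);
  v[2] = r * z;
}

// ---------------------------------------------------------------------------
// observables (used by production runs and exported for cross-checking
// against the plain-R morphology implementation)

static const int NOBS = 20;
static const char* OBS_NAMES[NOBS] = {
  "rg2_all", "rg2_S", "rg2_F",
  "lam1_all", "lam2_all", "lam3_all",
  "lam1_S", "lam2_S", "lam3_S",
  "lam1_F", "lam2_F", "lam3_F",
  "s_nem", "s_planar", "nss", "nff", "nsf", "ext_S", "n_folds", "demix"};

// eigenvalues of a symmetric 3x3 matrix, descending
static void eig3sym(double a11, double a22, double a33, double a12, double a13,
                    double a23, double out[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-300) {
    out[0] = a11; out[1] = a22; out[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    r = std::min(1.0, std::max(-1.0, r));
    double phi = std::acos(r) / 3.0;
    out[0] = q + 2.0 * p * std::cos(phi);
    out[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    out[1] = 3.0 * q - out[0] - out[2];
  }
  std::sort(out, out + 3, std::greater<double>());
}

// gyration tensor eigenvalues of a bead subset; returns rg2 (= trace)
static double gyr_subset(const double* p, const std::vector<int>& idx,
                         double lam[3]) {
  int n = (int)idx.size();
  lam[0] = lam[1] = lam[2] = 0.0;
  if (n == 0) return 0.0;
  double c[3] = {0, 0, 0};
  for (int i : idx)
    for (int a = 0; a < 3; ++a) c[a] += p[3 * i + a];
  for (int a = 0; a < 3; ++a) c[a] /= n;
  double g[6] = {0, 0, 0, 0, 0, 0};  // xx yy zz xy xz yz
  for (int i : idx) {
    double d[3];
    for (int a = 0; a < 3; ++a) d[a] = p[3 * i + a] - c[a];
    g[0] += d[0] * d[0]; g[1] += d[1] * d[1]; g[2] += d[2] * d[2];
    g[3] += d[0] * d[1]; g[4] += d[0] * d[2]; g[5] += d[1] * d[2];
  }
  for (int a = 0; a < 6; ++a) g[a] /= n;
  eig3sym(g[0], g[1], g[2], g[3], g[4], g[5], lam);
  return g[0] + g[1] + g[2];
}

static void compute_obs(const double* p, const Model& M, int nss, int nff,
                        int nsf, double* out) {
  std::vector<int> all, is, fs;
  for (int i = 0; i < M.N; ++i) {
    all.push_back(i);
    if (M.type[i]) is.push_back(i); else fs.push_back(i);
  }
  double lamA[3], lamS[3], lamF[3];
  out[0] = gyr_subset(p, all, lamA);
  out[1] = gyr_subset(p, is, lamS);
  out[2] = gyr_subset(p, fs, lamF);
  out[3] = lamA[0]; out[4] = lamA[1]; out[5] = lamA[2];
  out[6] = lamS[0]; out[7] = lamS[1]; out[8] = lamS[2];
  out[9] = lamF[0]; out[10] = lamF[1]; out[11] = lamF[2];
  // nematic order of S-block bonds: largest eigenvalue of Q
  double q[6] = {0, 0, 0, 0, 0, 0};
  int nb = 0;
  for (int i = 0; i < M.N - 1; ++i) {
    if (!(M.type[i] && M.type[i + 1])) continue;
    double u[3];
    double nn = 0;
    for (int a = 0; a < 3; ++a) {
      u[a] = p[3 * (i + 1) + a] - p[3 * i + a];
      nn += u[a] * u[a];
    }
    nn = std::sqrt(nn);
    for (int a = 0; a < 3; ++a) u[a] /= nn;
    q[0] += 1.5 * u[0] * u[0] - 0.5; q[1] += 1.5 * u[1] * u[1] - 0.5;
    q[2] += 1.5 * u[2] * u[2] - 0.5;
    q[3] += 1.5 * u[0] * u[1]; q[4] += 1.5 * u[0] * u[2];
    q[5] += 1.5 * u[1] * u[2];
    nb++;
  }
  if (nb > 0) {
    for (int a = 0; a < 6; ++a) q[a] /= nb;
    double lq[3];
    eig3sym(q[0], q[1], q[2], q[3], q[4], q[5], lq);
    out[12] = lq[0];
    out[13] = -lq[2];
  } else { out[12] = 0.0; out[13] = 0.0; }
  out[14] = nss; out[15] = nff; out[16] = nsf;
  // mean end-to-end / contour ratio over S blocks (contiguous S runs, len >= 2)
  double extsum = 0; int nruns = 0;
  int i = 0;
  while (i < M.N) {
    if (M.type[i]) {
      int j = i;
      while (j + 1 < M.N && M.type[j + 1]) j++;
      if (j > i) {
        double ete = std::sqrt(pdist2(p, i, j));
        double cont = 0;
        for (int m = i; m < j; ++m) cont += std::sqrt(pdist2(p, m, m + 1));
        extsum += ete / cont;
        nruns++;
      }
      i = j + 1;
    } else i++;
  }
  out[17] = nruns ? extsum / nruns : 0.0;
  // sharp folds: eligible angles with theta < 90 deg (cos > 0)
  int folds = 0;
  for (int c = 1; c <= M.N - 2; ++c) {
    if (!M.angok[c]) continue;
    double ax = p[3 * (c - 1)] - p[3 * c], ay = p[3 * (c - 1) + 1] - p[3 * c + 1],
           az = p[3 * (c - 1) + 2] - p[3 * c + 2];
    double bx = p[3 * (c + 1)] - p[3 * c], by = p[3 * (c + 1) + 1] - p[3 * c + 1],
           bz = p[3 * (c + 1) + 2] - p[3 * c + 2];
    if (ax * bx + ay * by + az * bz > 0) folds++;
  }
  out[18] = folds;
  int tot = nss + nff + nsf;
  out[19] = tot ? (double)nsf / tot : 0.0;
}

// ---------------------------------------------------------------------------
// sampler engine

enum Mode { SAMC, FROZEN, METRO };

struct Sampler {
  Model M;
  std::vector<double> p;
  int envraw, nst, nss, nff, nsf;
  int nE, nS;
  std::vector<double> logg, visits;
  std::vector<int> vkeys;
  double cur_min;
  Mode mode;
  double gamma;
  double Tmet, eps_st, raw_scale;  // Metropolis only
  long long ntrial, acc_loc, try_loc, acc_rg, try_rg, rej_offsupport;

  inline int kidx(int e_raw, int s) const { return (-e_raw) + nE * s; }

  void recompute_min() {
    if (vkeys.empty()) { cur_min = 0.0; return; }
    double mn = R_PosInf;
    for (int id : vkeys)
      if (logg[id] < mn) mn = logg[id];
    cur_min = mn;
  }

  bool decide(int e_new, int s_new) {
    if (mode == METRO) {
      double dU = raw_scale * (double)(e_new - envraw) +
                  eps_st * (double)(s_new - nst);
      if (dU <= 0) return true;
      return unif_rand() < std::exp(-dU / Tmet);
    }
    double lgold = logg[kidx(envraw, nst)];
    double lgnew = logg[kidx(e_new, s_new)];
    if (ISNAN(lgnew)) {
      if (mode == FROZEN) { rej_offsupport++; return false; }
      // unseen macrostate: register at the log-density of the state it is
      // entered from, so the estimated landscape stays locally smooth and
      // the move is accepted
      int id = kidx(e_new, s_new);
      logg[id] = lgold;
      vkeys.push_back(id);
      return true;
    }
    if (lgnew <= lgold) return true;
    return unif_rand() < std::exp(lgold - lgnew);
  }

  void update_current() {
    if (mode == METRO) return;
    int id = kidx(envraw, nst);
    if (mode == SAMC) logg[id] += gamma;
    visits[id] += 1.0;
  }

  void register_current() {
    int id = kidx(envraw, nst);
    if (ISNAN(logg[id])) {
      if (vkeys.empty()) cur_min = 0.0; else recompute_min();
      logg[id] = cur_min;
      vkeys.push_back(id);
    }
  }

  void trial_local() {
    try_loc++;
    int i = (int)(unif_rand() * M.N);
    if (i >= M.N) i = M.N - 1;
    double np_[3];
    for (int a = 0; a < 3; ++a)
      np_[a] = p[3 * i + a] + (2.0 * unif_rand() - 1.0) * M.step;
    bool valid = true;
    for (int j = i - 1; j <= i + 1; j += 2) {
      if (j < 0 || j >= M.N) continue;
      double dx = np_[0] - p[3 * j], dy = np_[1] - p[3 * j + 1],
             dz = np_[2] - p[3 * j + 2];
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < M.lmin2 || dd > M.lmax2) { valid = false; break; }
    }
    int denv = 0, dnst = 0, dnss = 0, dnff = 0, dnsf = 0;
    if (valid && !M.phantom) {
      int ti = M.type[i];
      for (int j = 0; j < M.N; ++j) {
        if (j >= i - 1 && j <= i + 1) continue;
        double dx = np_[0] - p[3 * j], dy = np_[1] - p[3 * j + 1],
               dz = np_[2] - p[3 * j + 2];
        double d2n = dx * dx + dy * dy + dz * dz;
        if (d2n < M.sigma2) { valid = false; break; }
        double d2o = pdist2(p.data(), i, j);
        bool co = d2o <= M.rcut2, cn = d2n <= M.rcut2;
        if (co != cn) {
          int tj = M.type[j], sgn = cn ? 1 : -1;
          denv += sgn * M.eps[ti][tj];
          if (ti && tj) dnss += sgn;
          else if (!ti && !tj) dnff += sgn;
          else dnsf += sgn;
        }
      }
    }
    bool accepted = false;
    double old_[3];
    if (valid) {
      int c0 = std::max(1, i - 1), c1 = std::min(M.N - 2, i + 1);
      int oldf = 0, newf = 0;
      for (int c = c0; c <= c1; ++c)
        if (M.angok[c] && ang_fav(p.data(), M, c)) oldf++;
      for (int a = 0; a < 3; ++a) { old_[a] = p[3 * i + a]; p[3 * i + a] = np_[a]; }
      for (int c = c0; c <= c1; ++c)
        if (M.angok[c] && ang_fav(p.data(), M, c)) newf++;
      dnst = newf - oldf;
      int e_new = envraw + denv, s_new = nst + dnst;
      accepted = decide(e_new, s_new);
      if (accepted) {
        envraw = e_new; nst = s_new;
        nss += dnss; nff += dnff; nsf += dnsf;
        acc_loc++;
      } else {
        for (int a = 0; a < 3; ++a) p[3 * i + a] = old_[a];
      }
    }
    update_current();
  }

  // contact-energy contribution of all non-bonded pairs touching [lo, hi]
  void part_env(int lo, int hi, int& env, int& pss, int& pff, int& psf) {
    env = 0; pss = pff = psf = 0;
    if (M.phantom) return;
    for (int r = lo; r <= hi; ++r)
      for (int j = 0; j < M.N; ++j) {
        if (j >= r - 1 && j <= r + 1) continue;
        if (j >= lo && j <= hi && j < r) continue;  // in-segment pair once
        if (pdist2(p.data(), r, j) <= M.rcut2) {
          int ti = M.type[r], tj = M.type[j];
          env += M.eps[ti][tj];
          if (ti && tj) pss++;
          else if (!ti && !tj) pff++;
          else psf++;
        }
      }
  }

  bool part_overlap(int lo, int hi) {
    if (M.phantom) return false;
    for (int r = lo; r <= hi; ++r)
      for (int j = 0; j < M.N; ++j) {
        if (j >= r - 1 && j <= r + 1) continue;
        if (j >= lo && j <= hi && j < r) continue;
        if (pdist2(p.data(), r, j) < M.sigma2) return true;
      }
    return false;
  }

  int part_ang(int lo, int hi) {
    int c0 = std::max(1, lo - 1), c1 = std::min(M.N - 2, hi + 1);
    int f = 0;
    for (int c = c0; c <= c1; ++c)
      if (M.angok[c] && ang_fav(p.data(), M, c)) f++;
    return f;
  }

  void trial_regrow() {
    try_rg++;
    int kmax = std::min(M.kmax, M.N - 1);
    int k = 1 + (int)(unif_rand() * kmax);
    if (k > kmax) k = kmax;
    bool tail = unif_rand() < 0.5;
    int lo = tail ? M.N - k : 0;
    int hi = tail ? M.N - 1 : k - 1;
    int o_env, o_ss, o_ff, o_sf;
    part_env(lo, hi, o_env, o_ss, o_ff, o_sf);
    int o_f = part_ang(lo, hi);
    std::vector<double> saved(p.begin() + 3 * lo, p.begin() + 3 * (hi + 1));
    double v[3];
    if (tail)
      for (int m = lo; m <= hi; ++m) {
        shell_vec(M, v);
        for (int a = 0; a < 3; ++a) p[3 * m + a] = p[3 * (m - 1) + a] + v[a];
      }
    else
      for (int m = hi; m >= lo; --m) {
        shell_vec(M, v);
        for (int a = 0; a < 3; ++a) p[3 * m + a] = p[3 * (m + 1) + a] + v[a];
      }
    bool accepted = false;
    if (!part_overlap(lo, hi)) {
      int n_env, n_ss, n_ff, n_sf;
      part_env(lo, hi, n_env, n_ss, n_ff, n_sf);
      int n_f = part_ang(lo, hi);
      int e_new = envraw + n_env - o_env;
      int s_new = nst + n_f - o_f;
      accepted = decide(e_new, s_new);
      if (accepted) {
        envraw = e_new; nst = s_new;
        nss += n_ss - o_ss; nff += n_ff - o_ff; nsf += n_sf - o_sf;
        acc_rg++;
      }
    }
    if (!accepted) std::copy(saved.begin(), saved.end(), p.begin() + 3 * lo);
    update_current();
  }

  void init(NumericMatrix coords, const List& model) {
    M = build_model(model);
    p.resize(3 * M.N);
    for (int i = 0; i < M.N; ++i)
      for (int a = 0; a < 3; ++a) p[3 * i + a] = coords(i, a);
    nE = M.envcap + 1; nS = M.nstmax + 1;
    logg.assign((size_t)nE * nS, NA_REAL);
    visits.assign((size_t)nE * nS, 0.0);
    cur_min = 0.0;
    ntrial = acc_loc = try_loc = acc_rg = try_rg = rej_offsupport = 0;
    full_counts(p.data(), M, envraw, nst, nss, nff, nsf);
  }

  void load_dos(IntegerVector ke, IntegerVector ks, NumericVector kl,
                NumericVector kv) {
    for (int i = 0; i < ke.size(); ++i) {
      if (-ke[i] < 0 || -ke[i] >= nE || ks[i] < 0 || ks[i] >= nS)
        stop("DoS key (%d, %d) outside the model's macrostate bounds", ke[i], ks[i]);
      int id = kidx(ke[i], ks[i]);
      logg[id] = kl[i];
      if (kv.size() == ke.size()) visits[id] = kv[i];
      vkeys.push_back(id);
    }
    recompute_min();
  }

  List dos_out() const {
    std::vector<int> keys(vkeys);
    std::sort(keys.begin(), keys.end());
    int n = (int)keys.size();
    IntegerVector oe(n), os(n);
    NumericVector ol(n), ov(n);
    for (int i = 0; i < n; ++i) {
      oe[i] = -(keys[i] % nE);
      os[i] = keys[i] / nE;
      ol[i] = logg[keys[i]];
      ov[i] = visits[keys[i]];
    }
    NumericMatrix co(M.N, 3);
    for (int i = 0; i < M.N; ++i)
      for (int a = 0; a < 3; ++a) co(i, a) = p[3 * i + a];
    return List::create(
        _["Env_raw"] = oe, _["nst"] = os, _["log_g"] = ol, _["visits"] = ov,
        _["coords"] = co,
        _["acc_local"] = try_loc ? (double)acc_loc / try_loc : NA_REAL,
        _["acc_regrow"] = try_rg ? (double)acc_rg / try_rg : NA_REAL,
        _["rej_offsupport"] = (double)rej_offsupport,
        _["Env_raw_final"] = envraw, _["nst_final"] = nst);
  }
};

// [[Rcpp::export]]
List cc_run_samc(NumericMatrix coords, List model, double gamma0, double t0,
                 double t_offset, double n_mcs, IntegerVector key_env,
                 IntegerVector key_nst, NumericVector key_logg,
                 NumericVector key_visits) {
  Sampler S;
  S.mode = SAMC;
  S.init(coords, model);
  S.load_dos(key_env, key_nst, key_logg, key_visits);
  if (n_mcs > 0) S.register_current();
  long long nm = (long long)n_mcs;
  int ntry = 2 * S.M.N;
  for (long long t = 1; t <= nm; ++t) {
    double tt = t_offset + (double)t;
    S.gamma = gamma0 * std::min(1.0, t0 / tt);
    for (int j = 0; j < ntry; ++j) S.trial_local();
    S.trial_regrow();
    if ((t & 16383) == 0) Rcpp::checkUserInterrupt();
  }
  return S.dos_out();
}

// [[Rcpp::export]]
List cc_production(NumericMatrix coords, List model, double n_mcs,
                   int sample_every, IntegerVector key_env,
                   IntegerVector key_nst, NumericVector key_logg) {
  Sampler S;
  S.mode = FROZEN;
  S.init(coords, model);
  S.load_dos(key_env, key_nst, key_logg, NumericVector(0));
  // ensure the starting macrostate is usable even if outside the support
  int id0 = S.kidx(S.envraw, S.nst);
  bool off0 = ISNAN(S.logg[id0]);
  if (off0) { S.logg[id0] = S.cur_min; S.vkeys.push_back(id0); }
  size_t nk = (size_t)S.nE * S.nS;
  std::vector<double> acc(nk * NOBS, 0.0), cnt(nk, 0.0);
  double obs[NOBS];
  long long nm = (long long)n_mcs;
  int ntry = 2 * S.M.N;
  for (long long t = 1; t <= nm; ++t) {
    for (int j = 0; j < ntry; ++j) S.trial_local();
    S.trial_regrow();
    if (t % sample_every == 0) {
      compute_obs(S.p.data(), S.M, S.nss, S.nff, S.nsf, obs);
      int id = S.kidx(S.envraw, S.nst);
      cnt[id] += 1.0;
      for (int a = 0; a < NOBS; ++a) acc[(size_t)id * NOBS + a] += obs[a];
    }
    if ((t & 16383) == 0) Rcpp::checkUserInterrupt();
  }
  // collect keys with any samples or visits
  std::vector<int> keys;
  for (int id : S.vkeys)
    if (cnt[id] > 0 || S.visits[id] > 0) keys.push_back(id);
  std::sort(keys.begin(), keys.end());
  int n = (int)keys.size();
  IntegerVector oe(n), os(n);
  NumericVector ocnt(n), ovis(n);
  NumericMatrix om(n, NOBS);
  for (int i = 0; i < n; ++i) {
    int id = keys[i];
    oe[i] = -(id % S.nE);
    os[i] = id / S.nE;
    ocnt[i] = cnt[id];
    ovis[i] = S.visits[id];
    for (int a = 0; a < NOBS; ++a)
      om(i, a) = cnt[id] > 0 ? acc[(size_t)id * NOBS + a] / cnt[id] : NA_REAL;
  }
  colnames(om) = CharacterVector(OBS_NAMES, OBS_NAMES + NOBS);
  NumericMatrix co(S.M.N, 3);
  for (int i = 0; i < S.M.N; ++i)
    for (int a = 0; a < 3; ++a) co(i, a) = S.p[3 * i + a];
  return List::create(
      _["Env_raw"] = oe, _["nst"] = os, _["count"] = ocnt, _["visits"] = ovis,
      _["means"] = om, _["coords"] = co,
      _["acc_local"] = S.try_loc ? (double)S.acc_loc / S.try_loc : NA_REAL,
      _["acc_regrow"] = S.try_rg ? (double)S.acc_rg / S.try_rg : NA_REAL,
      _["rej_offsupport"] = (double)S.rej_offsupport,
      _["start_offsupport"] = off0);
}

// [[Rcpp::export]]
List cc_metropolis(NumericMatrix coords, List model, double temperature,
                   double eps_st, double raw_scale, double n_mcs,
                   int sample_every) {
  Sampler S;
  S.mode = METRO;
  S.init(coords, model);
  S.Tmet = temperature;
  S.eps_st = eps_st;
  S.raw_scale = raw_scale;
  long long nm = (long long)n_mcs;
  int ntry = 2 * S.M.N;
  int nrow = (int)(nm / sample_every);
  NumericMatrix out(nrow, 6);
  colnames(out) = CharacterVector::create("U", "Env_raw", "nst", "rg2_all",
                                          "rg2_S", "rg2_F");
  int r = 0;
  std::vector<int> all, is, fs;
  for (int i = 0; i < S.M.N; ++i) {
    all.push_back(i);
    if (S.M.type[i]) is.push_back(i); else fs.push_back(i);
  }
  double lam[3];
  for (long long t = 1; t <= nm; ++t) {
    for (int j = 0; j < ntry; ++j) S.trial_local();
    S.trial_regrow();
    if (t % sample_every == 0 && r < nrow) {
      out(r, 0) = raw_scale * S.envraw + eps_st * S.nst;
      out(r, 1) = S.envraw;
      out(r, 2) = S.nst;
      out(r, 3) = gyr_subset(S.p.data(), all, lam);
      out(r, 4) = gyr_subset(S.p.data(), is, lam);
      out(r, 5) = gyr_subset(S.p.data(), fs, lam);
      r++;
    }
    if ((t & 16383) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix co(S.M.N, 3);
  for (int i = 0; i < S.M.N; ++i)
    for (int a = 0; a < 3; ++a) co(i, a) = S.p[3 * i + a];
  return List::create(
      _["samples"] = out, _["coords"] = co,
      _["acc_local"] = S.try_loc ? (double)S.acc_loc / S.try_loc : NA_REAL,
      _["acc_regrow"] = S.try_rg ? (double)S.acc_rg / S.try_rg : NA_REAL);
}

// uniform shell-volume chain growth with hard-sphere rejection
// [[Rcpp::export]]
List cc_brute_force(List model, double n_samples) {
  Model M = build_model(model);
  int nE = M.envcap + 1, nS = M.nstmax + 1;
  std::vector<double> counts((size_t)nE * nS, 0.0);
  std::vector<double> p(3 * M.N);
  double v[3];
  long long ns = (long long)n_samples, valid = 0;
  for (long long s = 0; s < ns; ++s) {
    p[0] = p[1] = p[2] = 0.0;
    bool ok = true;
    for (int m = 1; m < M.N && ok; ++m) {
      shell_vec(M, v);
      for (int a = 0; a < 3; ++a) p[3 * m + a] = p[3 * (m - 1) + a] + v[a];
      if (!M.phantom)
        for (int j = 0; j <= m - 2; ++j)
          if (pdist2(p.data(), m, j) < M.sigma2) { ok = false; break; }
    }
    if (!ok) continue;
    int envraw, nst, a1, a2, a3;
    full_counts(p.data(), M, envraw, nst, a1, a2, a3);
    counts[(-envraw) + (size_t)nE * nst] += 1.0;
    valid++;
    if ((s & 65535) == 0) Rcpp::checkUserInterrupt();
  }
  std::vector<int> keys;
  for (size_t id = 0; id < counts.size(); ++id)
    if (counts[id] > 0) keys.push_back((int)id);
  int n = (int)keys.size();
  IntegerVector oe(n), os(n);
  NumericVector oc(n);
  for (int i = 0; i < n; ++i) {
    oe[i] = -(keys[i] % nE);
    os[i] = keys[i] / nE;
    oc[i] = counts[keys[i]];
  }
  return List::create(_["Env_raw"] = oe, _["nst"] = os, _["count"] = oc,
                      _["n_valid"] = (double)valid,
                      _["n_samples"] = (double)ns);
}

// ---------------------------------------------------------------------------
// small exported helpers

// [[Rcpp::export]]
List cc_count_contacts(NumericMatrix coords, List model) {
  Model M = build_model(model);
  std::vector<double> p(3 * M.N);
  for (int i = 0; i < M.N; ++i)
    for (int a = 0; a < 3; ++a) p[3 * i + a] = coords(i, a);
  int envraw, nst, nss, nff, nsf;
  full_counts(p.data(), M, envraw, nst, nss, nff, nsf);
  return List::create(_["nss"] = nss, _["nff"] = nff, _["nsf"] = nsf,
                      _["nst"] = nst, _["Env_raw"] = envraw);
}

// [[Rcpp::export]]
List cc_validate(NumericMatrix coords, List model) {
  Model M = build_model(model);
  std::vector<double> p(3 * M.N);
  for (int i = 0; i < M.N; ++i)
    for (int a = 0; a < 3; ++a) p[3 * i + a] = coords(i, a);
  int kind;
  int where = full_validate(p.data(), M, kind);
  return List::create(_["valid"] = (kind == 0), _["kind"] = kind,
                      _["where"] = where);
}

// [[Rcpp::export]]
NumericVector cc_observables(NumericMatrix coords, List model) {
  Model M = build_model(model);
  std::vector<double> p(3 * M.N);
  for (int i = 0; i < M.N; ++i)
    for (int a = 0; a < 3; ++a) p[3 * i + a] = coords(i, a);
  int envraw, nst, nss, nff, nsf;
  full_counts(p.data(), M, envraw, nst, nss, nff, nsf);
  double obs[NOBS];
  compute_obs(p.data(), M, nss, nff, nsf, obs);
  NumericVector out(NOBS);
  out.names() = CharacterVector(OBS_NAMES, OBS_NAMES + NOBS);
  for (int a = 0; a < NOBS; ++a) out[a] = obs[a];
  return out;
}

// candidate from one local displacement (no acceptance step)
// [[Rcpp::export]]
List cc_propose_local(NumericMatrix coords, List model) {
  Model M = build_model(model);
  int i = (int)(unif_rand() * M.N);
  if (i >= M.N) i = M.N - 1;
  NumericMatrix cand = clone(coords);
  for (int a = 0; a < 3; ++a)
    cand(i, a) = coords(i, a) + (2.0 * unif_rand() - 1.0) * M.step;
  std::vector<double> p(3 * M.N);
  for (int k = 0; k < M.N; ++k)
    for (int a = 0; a < 3; ++a) p[3 * k + a] = cand(k, a);
  int kind;
  int where = full_validate(p.data(), M, kind);
  return List::create(_["coords"] = cand, _["bead"] = i + 1,
                      _["valid"] = (kind == 0));
}

// candidate from one end-cut-and-regrow (no acceptance step)
// [[Rcpp::export]]
List cc_propose_regrow(NumericMatrix coords, List model) {
  Model M = build_model(model);
  int kmax = std::min(M.kmax, M.N - 1);
  int k = 1 + (int)(unif_rand() * kmax);
  if (k > kmax) k = kmax;
  bool tail = unif_rand() < 0.5;
  NumericMatrix cand = clone(coords);
  double v[3];
  if (tail)
    for (int m = M.N - k; m <= M.N - 1; ++m) {
      shell_vec(M, v);
      for (int a = 0; a < 3; ++a) cand(m, a) = cand(m - 1, a) + v[a];
    }
  else
    for (int m = k - 1; m >= 0; --m) {
      shell_vec(M, v);
      for (int a = 0; a < 3; ++a) cand(m, a) = cand(m + 1, a) + v[a];
    }
  std::vector<double> p(3 * M.N);
  for (int q = 0; q < M.N; ++q)
    for (int a = 0; a < 3; ++a) p[3 * q + a] = cand(q, a);
  int kind;
  int where = full_validate(p.data(), M, kind);
  return List::create(_["coords"] = cand, _["k"] = k,
                      _["end"] = tail ? "tail" : "head",
                      _["valid"] = (kind == 0));
}

// one shell-volume-uniform bond vector (for distribution tests)
// [[Rcpp::export]]
NumericVector cc_shell_vec(List model) {
  Model M = build_model(model);
  double v[3];
  shell_vec(M, v);
  return NumericVector::create(v[0], v[1], v[2]);
}
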