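#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice geometry shared by all kernels below. Coordinates are 0-based,
// x indexes width (matrix rows), y indexes height (matrix columns).
struct Geom {
  int W, H;
  bool tx, ty;
  // returns false when (x, y) falls off a bounded axis; wraps otherwise
  inline bool canon(int &x, int &y) const {
    if (tx) { x %= W; if (x < 0) x += W; }
    else if (x < 0 || x >= W) return false;
    if (ty) { y %= H; if (y < 0) y += H; }
    else if (y < 0 || y >= H) return false;
    return true;
  }
};

// Geometric mean of activity over (x, y) and its same-cell kernel
// neighbors; 0 for background sites or when any factor is 0.
static double act_gm(const IntegerMatrix &id, const IntegerMatrix &act,
                     const Geom &g, const IntegerMatrix &kern,
                     int x, int y) {
  int c = id(x, y);
  if (c == 0) return 0.0;
  double logsum = 0.0;
  int n = 0;
  int a0 = act(x, y);
  if (a0 == 0) return 0.0;
  logsum += std::log((double)a0); n++;
  for (int r = 0; r < kern.nrow(); r++) {
    int nx = x + kern(r, 0), ny = y + kern(r, 1);
    if (!g.canon(nx, ny)) continue;
    if (id(nx, ny) != c) continue;
    int a = act(nx, ny);
    if (a == 0) return 0.0;
    logsum += std::log((double)a); n++;
  }
  return std::exp(logsum / n);
}

// Incremental energy change of copying the identity at (sx, sy) onto
// (tx_, ty_). perim may be NULL when no perimeter term is active.
static double delta_h_core(const IntegerMatrix &id, const IntegerMatrix &act,
                           const IntegerVector &kind_of,
                           const NumericVector &vol,
                           const NumericVector &tv_of,
                           const double *perim,
                           const NumericMatrix &J,
                           const NumericVector &lambda_v,
                           const NumericVector &target_v,
                           const NumericVector &lambda_p,
                           const NumericVector &target_p,
                           const NumericVector &lambda_act,
                           const NumericVector &max_act,
                           const Geom &g, const IntegerMatrix &kern,
                           int sx, int sy, int tx_, int ty_) {
  int is = id(sx, sy), it = id(tx_, ty_);
  int ks = kind_of[is], kt = kind_of[it];
  double dH = 0.0;

  // adhesion + neighbor tallies for the perimeter delta
  int K_t = 0, n_in_s = 0, n_in_t = 0;
  for (int r = 0; r < kern.nrow(); r++) {
    int nx = tx_ + kern(r, 0), ny = ty_ + kern(r, 1);
    if (!g.canon(nx, ny)) continue;
    K_t++;
    int in = id(nx, ny);
    if (in == is) n_in_s++;
    if (in == it) n_in_t++;
    int kn = kind_of[in];
    if (in != it) dH -= J(kt, kn);
    if (in != is) dH += J(ks, kn);
  }

  // quadratic volume elasticity (per-cell target overrides kind default)
  if (is != 0 && lambda_v[ks] > 0) {
    double tv = R_IsNA(tv_of[is]) ? target_v[ks] : tv_of[is];
    double v = vol[is];
    dH += lambda_v[ks] * ((v + 1 - tv) * (v + 1 - tv) - (v - tv) * (v - tv));
  }
  if (it != 0 && lambda_v[kt] > 0) {
    double tv = R_IsNA(tv_of[it]) ? target_v[kt] : tv_of[it];
    double v = vol[it];
    dH += lambda_v[kt] * ((v - 1 - tv) * (v - 1 - tv) - (v - tv) * (v - tv));
  }

  // quadratic perimeter elasticity
  if (perim) {
    if (is != 0 && lambda_p[ks] > 0) {
      double dp = K_t - 2.0 * n_in_s;
      double p = perim[is], tp = target_p[ks];
      dH += lambda_p[ks] * ((p + dp - tp) * (p + dp - tp) - (p - tp) * (p - tp));
    }
    if (it != 0 && lambda_p[kt] > 0) {
      double dp = 2.0 * n_in_t - K_t;
      double p = perim[it], tp = target_p[kt];
      dH += lambda_p[kt] * ((p + dp - tp) * (p + dp - tp) - (p - tp) * (p - tp));
    }
  }

  // Act protrusion term (source kind's params when enabled, else target's)
  int ka = -1;
  if (is != 0 && max_act[ks] > 0) ka = ks;
  else if (it != 0 && max_act[kt] > 0) ka = kt;
  if (ka >= 0 && lambda_act[ka] > 0) {
    double gs = act_gm(id, act, g, kern, sx, sy);
    double gt = act_gm(id, act, g, kern, tx_, ty_);
    dH += -(lambda_act[ka] / max_act[ka]) * (gs - gt);
  }
  return dH;
}

// [[Rcpp::export]]
NumericVector cpp_perimeters(IntegerMatrix identity, IntegerMatrix kernel,
                             bool torus_x, bool torus_y, int n_cells) {
  Geom g{identity.nrow(), identity.ncol(), torus_x, torus_y};
  NumericVector p(n_cells);
  for (int x = 0; x < g.W; x++)
    for (int y = 0; y < g.H; y++) {
      int c = identity(x, y);
      if (c == 0) continue;
      for (int r = 0; r < kernel.nrow(); r++) {
        int nx = x + kernel(r, 0), ny = y + kernel(r, 1);
        if (!g.canon(nx, ny)) continue;
        if (identity(nx, ny) != c) p[c] += 1;
      }
    }
  return p;
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix identity, IntegerMatrix activity,
                   IntegerVector kind_of, NumericVector volume_of,
                   NumericVector target_v_of, NumericVector perimeter_of,
                   NumericMatrix J,
                   NumericVector lambda_v, NumericVector target_v,
                   NumericVector lambda_p, NumericVector target_p,
                   NumericVector lambda_act, NumericVector max_act,
                   bool torus_x, bool torus_y, IntegerMatrix kernel,
                   int sx, int sy, int tx, int ty) {
  Geom g{identity.nrow(), identity.ncol(), torus_x, torus_y};
  return delta_h_core(identity, activity, kind_of, volume_of, target_v_of,
                      REAL(perimeter_of), J, lambda_v, target_v,
                      lambda_p, target_p, lambda_act, max_act,
                      g, kernel, sx, sy, tx, ty);
}

// Run n_mcs Monte Carlo Steps. One MCS = W*H copy-attempt resolutions
// (null attempts consume a slot), followed by an activity decay of 1.
// Uses R's RNG; mutates nothing passed in (inputs are cloned).
// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix identity_, IntegerMatrix activity_,
                 IntegerVector kind_of, NumericVector volume_of_,
                 NumericVector target_v_of, LogicalVector immutable_kind,
                 NumericMatrix J,
                 NumericVector lambda_v, NumericVector target_v,
                 NumericVector lambda_p, NumericVector target_p,
                 NumericVector lambda_act, NumericVector max_act,
                 double temperature, bool torus_x, bool torus_y,
                 IntegerMatrix kernel, int n_mcs) {
  IntegerMatrix id = clone(identity_);
  IntegerMatrix act = clone(activity_);
  NumericVector vol = clone(volume_of_);
  Geom g{id.nrow(), id.ncol(), torus_x, torus_y};
  const int W = g.W, H = g.H, N = W * H, K = kernel.nrow();
  const int n_cells = kind_of.size();
  const bool use_act = is_true(any(lambda_act > 0));
  const bool use_perim = is_true(any(lambda_p > 0));

  // incremental per-cell perimeter bookkeeping (only when needed)
  std::vector<double> perim;
  if (use_perim) {
    NumericVector p0 = cpp_perimeters(id, kernel, torus_x, torus_y, n_cells);
    perim.assign(p0.begin(), p0.end());
  }

  long long attempts = 0, accepted = 0, nulls = 0;
  for (int mcs = 0; mcs < n_mcs; mcs++) {
    for (int rep = 0; rep < N; rep++) {
      attempts++;
      int t = (int)(unif_rand() * N); if (t >= N) t = N - 1;
      int txx = t % W, tyy = t / W;
      int r = (int)(unif_rand() * K); if (r >= K) r = K - 1;
      int sxx = txx + kernel(r, 0), syy = tyy + kernel(r, 1);
      if (!g.canon(sxx, syy)) { nulls++; continue; }
      int is = id(sxx, syy), it = id(txx, tyy);
      if (is == it) { nulls++; continue; }
      if (immutable_kind[kind_of[it]] || immutable_kind[kind_of[is]]) {
        nulls++; continue;
      }
      double dH = delta_h_core(id, act, kind_of, vol, target_v_of,
                               use_perim ? perim.data() : (double *)nullptr,
                               J, lambda_v, target_v, lambda_p, target_p,
                               lambda_act, max_act, g, kernel,
                               sxx, syy, txx, tyy);
      bool ok = dH <= 0 || unif_rand() < std::exp(-dH / temperature);
      if (!ok) continue;
      accepted++;
      if (use_perim) {
        int K_t = 0, n_in_s = 0, n_in_t = 0;
        for (int rr = 0; rr < K; rr++) {
          int nx = txx + kernel(rr, 0), ny = tyy + kernel(rr, 1);
          if (!g.canon(nx, ny)) continue;
          K_t++;
          int in = id(nx, ny);
          if (in == is) n_in_s++;
          if (in == it) n_in_t++;
        }
        if (is != 0) perim[is] += K_t - 2.0 * n_in_s;
        if (it != 0) perim[it] += 2.0 * n_in_t - K_t;
      }
      id(txx, tyy) = is;
      vol[it] -= 1; vol[is] += 1;
      act(txx, tyy) = (is == 0) ? 0 : (int)max_act[kind_of[is]];
    }
    if (use_act) {
      for (int i = 0; i < N; i++)
        if (act[i] > 0) act[i] -= 1;
    }
  }

  NumericVector perim_out(n_cells);
  if (use_perim) perim_out = NumericVector(perim.begin(), perim.end());
  return List::create(_["identity"] = id, _["activity"] = act,
                      _["volume_of"] = vol, _["perimeter_of"] = perim_out,
                      _["n_attempts"] = (double)attempts,
                      _["n_accepted"] = (double)accepted,
                      _["n_null"] = (double)nulls);
}

// Count of unordered kernel-neighbor pixel pairs whose identities belong to
// two different non-background kinds (the heterotypic interface length).
// [[Rcpp::export]]
double cpp_heterotypic_interface(IntegerMatrix identity, IntegerVector kind_of,
                                 IntegerMatrix kernel,
                                 bool torus_x, bool torus_y) {
  Geom g{identity.nrow(), identity.ncol(), torus_x, torus_y};
  double n = 0;
  for (int x = 0; x < g.W; x++)
    for (int y = 0; y < g.H; y++) {
      int a = identity(x, y);
      if (a == 0) continue;
      for (int r = 0; r < kernel.nrow(); r++) {
        int dx = kernel(r, 0), dy = kernel(r, 1);
        if (dy < 0 || (dy == 0 && dx <= 0)) continue;  // half-kernel: once
        int nx = x + dx, ny = y + dy;
        if (!g.canon(nx, ny)) continue;
        int b = identity(nx, ny);
        if (b == 0) continue;
        if (kind_of[a] != kind_of[b]) n += 1;
      }
    }
  return n;
}
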