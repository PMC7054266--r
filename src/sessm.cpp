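#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Discretized decision-variable grid shared by the propagation engine.
// Grid points sit at i*dx for i in [-K, K]; states with |x| >= x_th are
// absorbing (transition-matrix diagonal 1, everything else 0), interior
// states receive a Gaussian step kernel with drift-dependent mean shift.

static inline int grid_halfwidth(double x_th, double s, double dx, double dt,
                                 double pad) {
  return (int)std::ceil((x_th + pad * s * std::sqrt(dt)) / dx - 1e-9);
}

// [[Rcpp::export(name = ".fp_propagate_cpp")]]
List fp_propagate_cpp(double v, double b, int cflag, double x_th, double x_b,
                      double s, double dx, double dt, double t_max,
                      double pad, double stop_mass) {
  const int K = grid_halfwidth(x_th, s, dx, dt, pad);
  // first absorbing index on the upper side: smallest i with i*dx >= x_th
  const int K_th = (int)std::ceil(x_th / dx - 1e-9);
  if (K_th < 2)
    stop("degenerate grid: dx too coarse to host interior states for x_th");

  const int n_steps = (int)std::lround(t_max / dt);
  const double sigma = s * std::sqrt(dt);
  const double x0 = x_b * (1.0 - 2.0 * cflag);
  const int i0 = (int)std::lround(x0 / dx);
  if (std::abs(i0) >= K_th)
    stop("starting point |x_b| falls on or outside the decision threshold");

  // probability mass over interior states, indexed by grid index + K_th - 1
  const int n_int = 2 * K_th - 1;  // indices -K_th+1 .. K_th-1
  std::vector<double> p(n_int, 0.0), pn(n_int, 0.0);
  p[i0 + K_th - 1] = 1.0;

  NumericVector cdf_up(n_steps), cdf_lo(n_steps);
  double up = 0.0, lo = 0.0;

  // Gaussian kernel support: +/- 5 sigma around the mean shift
  const int reach = (int)std::ceil(5.0 * sigma / dx);
  const int L = 2 * reach + 3;
  std::vector<double> w(L), suf(L + 1), pre(L);
  int jlo = 0;
  bool have_kernel = false;

  int k = 0;
  for (; k < n_steps; ++k) {
    // kernel is fixed on non-conflict trials, time-varying under conflict
    if (!have_kernel || cflag) {
      const double d = k * dt;  // within-trial clock at the step start
      const double mu = v * (1.0 + cflag * b * d) * dt;
      const int jc = (int)std::lround(mu / dx);
      jlo = jc - reach - 1;
      double wsum = 0.0;
      for (int q = 0; q < L; ++q) {
        const double z = ((jlo + q) * dx - mu) / sigma;
        w[q] = std::exp(-0.5 * z * z);
        wsum += w[q];
      }
      suf[L] = 0.0;
      double acc = 0.0;
      for (int q = 0; q < L; ++q) w[q] /= wsum;
      for (int q = L - 1; q >= 0; --q) suf[q] = suf[q + 1] + w[q];
      for (int q = 0; q < L; ++q) { acc += w[q]; pre[q] = acc; }
      have_kernel = true;
    }

    std::fill(pn.begin(), pn.end(), 0.0);
    double *pnp = pn.data();
    const double *wp = w.data();
    for (int ii = 0; ii < n_int; ++ii) {
      const double pi = p[ii];
      if (pi <= 0.0) continue;
      const int gi = ii - (K_th - 1);  // grid index
      // upper absorption: kernel offsets j >= K_th - gi
      const int qu = (K_th - gi) - jlo;
      if (qu <= 0) { up += pi; continue; }
      if (qu <= L - 1) up += pi * suf[qu];
      // lower absorption: offsets j <= -K_th - gi
      const int ql = (-K_th - gi) - jlo;
      if (ql >= L - 1) { lo += pi; continue; }
      if (ql >= 0) lo += pi * pre[ql];
      // interior targets
      const int qlo = ql + 1 > 0 ? ql + 1 : 0;
      const int qhi = qu - 1 < L - 1 ? qu - 1 : L - 1;
      double *dst = pnp + (gi + jlo + qlo + K_th - 1);
      const double *ws = wp + qlo;
      const int m = qhi - qlo;
      for (int q = 0; q <= m; ++q) dst[q] += pi * ws[q];
    }
    p.swap(pn);
    cdf_up[k] = up;
    cdf_lo[k] = lo;
    // kernel columns are renormalized, so interior mass is 1 - absorbed
    if (1.0 - up - lo < stop_mass) { ++k; break; }
  }
  // mass is gone (or horizon reached): defective CDFs stay flat afterwards
  for (int kk = k; kk < n_steps; ++kk) { cdf_up[kk] = up; cdf_lo[kk] = lo; }

  double leak = 1.0 - up - lo;
  return List::create(_["cdf_up"] = cdf_up, _["cdf_lo"] = cdf_lo,
                      _["n_steps"] = n_steps, _["steps_used"] = k,
                      _["interior_mass"] = leak, _["K"] = K,
                      _["K_th"] = K_th);
}

// Euler-Maruyama simulation of individual decision-variable traces.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(double v, double b, int cflag, double x_th, double x_b,
                  double s, double t_nd, double s_t, int n, double dt,
                  double t_max, bool keep_traces) {
  RNGScope scope;
  const int max_steps = (int)std::lround(t_max / dt);
  const double sdt = s * std::sqrt(dt);
  const double x0 = x_b * (1.0 - 2.0 * cflag);

  NumericVector rt(n), decision_time(n), t_eff(n);
  LogicalVector correct(n), censored(n);
  std::vector<double> tvals;
  IntegerVector toff(keep_traces ? n + 1 : 1);
  if (keep_traces) { tvals.reserve((size_t)n * 64); toff[0] = 0; }

  for (int i = 0; i < n; ++i) {
    double x = x0;
    if (keep_traces) tvals.push_back(x);
    int k = 0;
    bool hit = false;
    for (; k < max_steps; ++k) {
      const double d = k * dt;
      x += v * (1.0 + cflag * b * d) * dt + sdt * norm_rand();
      if (keep_traces) tvals.push_back(x);
      if (x >= x_th || x <= -x_th) { hit = true; ++k; break; }
    }
    const double te = t_nd + (unif_rand() - 0.5) * s_t;
    t_eff[i] = te;
    decision_time[i] = k * dt;
    correct[i] = x >= x_th;
    censored[i] = !hit;
    rt[i] = k * dt + te;
    if (keep_traces) toff[i + 1] = (int)tvals.size();
  }

  List out = List::create(_["rt"] = rt, _["decision_time"] = decision_time,
                          _["t_eff"] = t_eff, _["correct"] = correct,
                          _["censored"] = censored);
  if (keep_traces) {
    out["trace_values"] = NumericVector(tvals.begin(), tvals.end());
    out["trace_offsets"] = toff;
  }
  return out;
}

// Response-locked averaging of selected traces: traces are aligned at their
// final (threshold-crossing) sample and averaged backwards in time.
// Returns reversed running sums and counts: element r corresponds to
// r steps before the crossing sample.
// [[Rcpp::export(name = ".aligned_sums_cpp")]]
List aligned_sums_cpp(NumericVector values, IntegerVector offsets,
                      IntegerVector sel) {
  int maxlen = 0;
  for (int q = 0; q < sel.size(); ++q) {
    const int i = sel[q] - 1;
    const int len = offsets[i + 1] - offsets[i];
    if (len > maxlen) maxlen = len;
  }
  NumericVector sums(maxlen);
  IntegerVector cnts(maxlen);
  for (int q = 0; q < sel.size(); ++q) {
    const int i = sel[q] - 1;
    const int a = offsets[i], z = offsets[i + 1];
    const int len = z - a;
    for (int r = 0; r < len; ++r) {
      sums[r] += values[z - 1 - r];
      cnts[r] += 1;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = cnts);
}

// 3D connected-component labelling (6- or 26-connectivity) by flood fill.
static IntegerVector label3d(const LogicalVector &mask, const IntegerVector &dim,
                             int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int cz = cur / (nx * ny);
      const int cy = (cur - cz * nx * ny) / nx;
      const int cx = cur - cz * nx * ny - cy * nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 &&
                std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            const int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            const int idx = x + nx * (y + ny * z);
            if (mask[idx] && !lab[idx]) {
              lab[idx] = next;
              stack.push_back(idx);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  return label3d(mask, dim, connectivity);
}

// Threshold-free cluster enhancement of the positive part of a 3D map.
// Midpoint Riemann sum over thresholds h_k = (k - 1/2) * dh up to max(map):
// each suprathreshold voxel accumulates extent^E * h^H * dh of the connected
// component containing it.
static NumericVector tfce_pos(const NumericVector &map, const IntegerVector &dim,
                              double E, double H, double dh, int connectivity) {
  const int n = map.size();
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (map[i] > mx) mx = map[i];
  if (mx <= 0.0 || dh <= 0.0) return out;
  const int nsteps = (int)std::ceil(mx / dh - 0.5 + 1e-12);
  LogicalVector sup(n);
  for (int k = 1; k <= nsteps; ++k) {
    const double h = (k - 0.5) * dh;
    bool any = false;
    for (int i = 0; i < n; ++i) {
      sup[i] = map[i] >= h;
      any = any || sup[i];
    }
    if (!any) break;
    IntegerVector lab = label3d(sup, dim, connectivity);
    const int ncomp = lab.attr("n_components");
    std::vector<int> extent(ncomp + 1, 0);
    for (int i = 0; i < n; ++i) if (lab[i]) ++extent[lab[i]];
    std::vector<double> add(ncomp + 1, 0.0);
    const double hH = std::pow(h, H);
    for (int c = 1; c <= ncomp; ++c)
      add[c] = std::pow((double)extent[c], E) * hH * dh;
    for (int i = 0; i < n; ++i) if (lab[i]) out[i] += add[lab[i]];
  }
  return out;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dim, double E,
                       double H, double dh, int connectivity) {
  const int n = map.size();
  NumericVector pos = tfce_pos(map, dim, E, H, dh, connectivity);
  NumericVector neg_in(n);
  for (int i = 0; i < n; ++i) neg_in[i] = -map[i];
  NumericVector neg = tfce_pos(neg_in, dim, E, H, dh, connectivity);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pos[i] - neg[i];
  return out;
}

// Open (full) discrete convolution, used for the uniform non-decision-time
// jitter kernel.
// [[Rcpp::export(name = ".conv_open_cpp")]]
NumericVector conv_open_cpp(NumericVector p, NumericVector w) {
  const int n = p.size(), m = w.size();
  NumericVector out(n + m - 1);
  for (int j = 0; j < m; ++j) {
    const double wj = w[j];
    if (wj == 0.0) continue;
    for (int i = 0; i < n; ++i) out[i + j] += wj * p[i];
  }
  return out;
}
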