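#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// type-7 quantile of buf[0..n-1] (buf is scratch, reordered in place)
static double quantile7(std::vector<double> &buf, double p) {
  const int n = (int)buf.size();
  if (n == 1) return buf[0];
  double h = p * (n - 1);
  int lo = (int)std::floor(h);
  if (lo >= n - 1) { lo = n - 1; h = (double)lo; }
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  double xlo = buf[lo];
  if (h == (double)lo) return xlo;
  double xhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return xlo + (h - lo) * (xhi - xlo);
}

// Rolling type-7 quantile along each row (time axis = columns).
// Centred window of k frames, truncated at the series ends.
// [[Rcpp::export(name = ".roll_quantile_rows")]]
NumericMatrix roll_quantile_rows(NumericMatrix x, int k, double p) {
  const int nr = x.nrow(), nc = x.ncol();
  if (k < 1) stop("window must be >= 1 frame");
  NumericMatrix out(nr, nc);
  const int half_lo = (k - 1) / 2, half_hi = k / 2;
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int a = std::max(0, j - half_lo), b = std::min(nc - 1, j + half_hi);
      buf.assign(b - a + 1, 0.0);
      for (int t = a; t <= b; ++t) buf[t - a] = x(i, t);
      out(i, j) = quantile7(buf, p);
    }
  }
  return out;
}

struct UF {
  std::vector<int> parent;
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// 8-connected component labelling of a position x time mask after closing
// temporal gaps of <= gap frames at each position. Labels are positive
// integers ordered by first frame then first position; 0 = background.
// Returned labels cover the gap-closed support.
// [[Rcpp::export(name = ".label_events")]]
IntegerMatrix label_events(LogicalMatrix mask, int gap) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // close temporal gaps per row
  LogicalMatrix closed(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int last_on = -1;
    for (int j = 0; j < nc; ++j) {
      if (mask(i, j)) {
        if (last_on >= 0 && j - last_on - 1 <= gap)
          for (int t = last_on + 1; t < j; ++t) closed(i, t) = true;
        closed(i, j) = true;
        last_on = j;
      }
    }
  }
  IntegerMatrix lab(nr, nc);
  UF uf;
  uf.parent.push_back(0);          // dummy for background
  int next = 1;
  // scan column-major (time outer) so prior neighbours are already labelled
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!closed(i, j)) continue;
      int best = 0;
      if (i > 0 && lab(i - 1, j)) best = lab(i - 1, j);
      if (j > 0) {
        for (int di = -1; di <= 1; ++di) {
          int r = i + di;
          if (r < 0 || r >= nr) continue;
          int l = lab(r, j - 1);
          if (l) {
            if (best) uf.unite(best, l); else best = l;
          }
        }
      }
      if (i > 0 && lab(i - 1, j) && best) uf.unite(best, lab(i - 1, j));
      if (!best) { best = next++; uf.parent.push_back(best); }
      lab(i, j) = best;
    }
  }
  // flatten + renumber in first-occurrence order (column-major scan)
  std::vector<int> remap(next, 0);
  int n_out = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j)) {
        int r = uf.find(lab(i, j));
        if (!remap[r]) remap[r] = ++n_out;
        lab(i, j) = remap[r];
      }
  return lab;
}

// Random sequential placement of w[i] x h[i] boxes (position cells x frames)
// on an n_x x n_t grid. A candidate is accepted when its box, dilated by
// pad_x cells and pad_t frames, hits no previously accepted support: this
// enforces "separated by >= pad_x cells in position OR >= pad_t frames in
// time" between supports. Origin of box i is drawn uniformly from
// [x_lo, x_hi] x [t_lo, t_hi] (0-based, box must fit in the grid). Returns a
// 2-column matrix of accepted origins, NA when the attempt budget ran out.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".place_boxes")]]
IntegerMatrix place_boxes(IntegerVector w, IntegerVector h,
                          IntegerVector x_lo, IntegerVector x_hi,
                          IntegerVector t_lo, IntegerVector t_hi,
                          int n_x, int n_t, int pad_x, int pad_t,
                          int max_attempts) {
  const int n = w.size();
  std::vector<uint8_t> occ((size_t)n_x * n_t, 0);
  IntegerMatrix out(n, 2);
  RNGScope scope;
  for (int e = 0; e < n; ++e) {
    out(e, 0) = NA_INTEGER; out(e, 1) = NA_INTEGER;
    int xl = x_lo[e], xh = x_hi[e], tl = t_lo[e], th = t_hi[e];
    if (xh < xl || th < tl || w[e] > n_x || h[e] > n_t) continue;
    for (int a = 0; a < max_attempts; ++a) {
      int x0 = xl + (int)(unif_rand() * (xh - xl + 1));
      int t0 = tl + (int)(unif_rand() * (th - tl + 1));
      if (x0 > xh) x0 = xh;
      if (t0 > th) t0 = th;
      int xa = std::max(0, x0 - pad_x), xb = std::min(n_x - 1, x0 + w[e] - 1 + pad_x);
      int ta = std::max(0, t0 - pad_t), tb = std::min(n_t - 1, t0 + h[e] - 1 + pad_t);
      bool free_spot = true;
      for (int t = ta; t <= tb && free_spot; ++t) {
        const uint8_t *col = &occ[(size_t)t * n_x];
        for (int x = xa; x <= xb; ++x)
          if (col[x]) { free_spot = false; break; }
      }
      if (!free_spot) continue;
      for (int t = t0; t < t0 + h[e]; ++t) {
        uint8_t *col = &occ[(size_t)t * n_x];
        for (int x = x0; x < x0 + w[e]; ++x) col[x] = 1;
      }
      out(e, 0) = x0; out(e, 1) = t0;
      break;
    }
  }
  return out;
}

// Multiplicative rasterisation of constriction events into a diameter matrix.
// m: n_positions x n_frames (positions at (i + 0.5) * spacing mm, 0-based i);
// times: frame times (s); events given per-event as onset/duration/amplitude
// plus piecewise-linear path knots (concatenated, offsets 0-based).
// The Gaussian cross-section (sd sigma mm) is truncated where the relative
// constriction falls below trunc_frac of the local width.
// [[Rcpp::export(name = ".render_dips")]]
void render_dips(NumericMatrix m, NumericVector times, double spacing,
                 NumericVector onset, NumericVector dur, NumericVector amp,
                 NumericVector knot_t, NumericVector knot_x,
                 IntegerVector knot_off, double sigma, double trunc_frac) {
  const int nr = m.nrow(), nc = m.ncol(), n = onset.size();
  for (int e = 0; e < n; ++e) {
    double t0 = onset[e], t1 = onset[e] + dur[e], a = amp[e];
    if (a <= 0) continue;
    double r = sigma * std::sqrt(2.0 * std::log(a / trunc_frac));
    if (!(r > 0)) continue;
    int k0 = knot_off[e], k1 = (e + 1 < n) ? knot_off[e + 1] : knot_t.size();
    for (int j = 0; j < nc; ++j) {
      double t = times[j];
      if (t < t0 || t >= t1) continue;
      // linear interpolation of the path, constant beyond end knots
      double pos;
      if (k1 - k0 == 1 || t <= knot_t[k0]) pos = knot_x[k0];
      else if (t >= knot_t[k1 - 1]) pos = knot_x[k1 - 1];
      else {
        int lo = k0;
        while (lo + 1 < k1 && knot_t[lo + 1] <= t) ++lo;
        double f = (t - knot_t[lo]) / (knot_t[lo + 1] - knot_t[lo]);
        pos = knot_x[lo] + f * (knot_x[lo + 1] - knot_x[lo]);
      }
      int ia = std::max(0, (int)std::floor((pos - r) / spacing - 0.5));
      int ib = std::min(nr - 1, (int)std::ceil((pos + r) / spacing - 0.5));
      for (int i = ia; i <= ib; ++i) {
        double d = (i + 0.5) * spacing - pos;
        if (std::fabs(d) > r) continue;
        double c = a * std::exp(-d * d / (2.0 * sigma * sigma));
        if (c >= trunc_frac) m(i, j) *= (1.0 - c);
      }
    }
  }
}
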