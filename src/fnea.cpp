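// Bottom-up pairwise region merging (Fractal Net Evolution) on a
// multi-band image. Segments carry running sums/sums-of-squares per band,
// a 4-edge perimeter, and a bounding box, so the heterogeneity increase of
// a candidate merge is O(bands). Merging follows local mutual-best-fitting
// with a deterministic ascending-id treatment order; a merge is accepted
// only while its cost stays below scale^2.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Graph {
  int npix, B;
  double shape_w, cmpct_w, scale2;
  std::vector<double> band_w;
  std::vector<char> alive;
  std::vector<int> n, l, minr, maxr, minc, maxc, parent;
  std::vector<double> sum, sumsq;          // npix * B, band-major per segment
  std::vector<std::map<int, int> > nb;     // neighbor id -> shared 4-edges
  // memoized best neighbor per segment, invalidated when the segment or
  // any of its neighbors changes
  std::vector<char> dirty;
  std::vector<int> best_id;
  std::vector<double> best_c;

  int find(int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  }

  inline double h_color_term(double s, double ss, int nn) const {
    double var = ss / nn - (s / nn) * (s / nn);
    if (var < 0) var = 0;                  // numerical guard
    return nn * std::sqrt(var);
  }

  // weighted color heterogeneity increase of merging a and b
  double d_color(int a, int b) const {
    double d = 0.0;
    int nm = n[a] + n[b];
    for (int k = 0; k < B; ++k) {
      double sa = sum[(size_t)a * B + k], sb = sum[(size_t)b * B + k];
      double qa = sumsq[(size_t)a * B + k], qb = sumsq[(size_t)b * B + k];
      d += band_w[k] * (h_color_term(sa + sb, qa + qb, nm) -
                        h_color_term(sa, qa, n[a]) -
                        h_color_term(sb, qb, n[b]));
    }
    return d;
  }

  double cost(int a, int b, int shared) const {
    double dc = d_color(a, b);
    double ds = 0.0;
    if (shape_w > 0) {
      int nm = n[a] + n[b];
      int lm = l[a] + l[b] - 2 * shared;
      double cmp_m = std::sqrt((double)nm) * lm;       // n * l / sqrt(n)
      double cmp_a = std::sqrt((double)n[a]) * l[a];
      double cmp_b = std::sqrt((double)n[b]) * l[b];
      int w_m = std::max(maxc[a], maxc[b]) - std::min(minc[a], minc[b]) + 1;
      int h_m = std::max(maxr[a], maxr[b]) - std::min(minr[a], minr[b]) + 1;
      double bb_m = 2.0 * (w_m + h_m);
      double bb_a = 2.0 * ((maxc[a] - minc[a] + 1) + (maxr[a] - minr[a] + 1));
      double bb_b = 2.0 * ((maxc[b] - minc[b] + 1) + (maxr[b] - minr[b] + 1));
      double smo_m = nm * lm / bb_m;
      double smo_a = n[a] * l[a] / bb_a;
      double smo_b = n[b] * l[b] / bb_b;
      ds = cmpct_w * (cmp_m - cmp_a - cmp_b) +
           (1.0 - cmpct_w) * (smo_m - smo_a - smo_b);
    }
    double c = (1.0 - shape_w) * dc + shape_w * ds;
    return c < 0 ? 0.0 : c;
  }

  // minimum-cost neighbor of a; ties resolved to the lower id by the
  // ascending map iteration order. Returns -1 if a has no neighbors.
  int best_neighbor(int a, double *best_cost) {
    if (!dirty[a]) { *best_cost = best_c[a]; return best_id[a]; }
    int best = -1;
    double bc = R_PosInf;
    for (std::map<int, int>::const_iterator it = nb[a].begin();
         it != nb[a].end(); ++it) {
      double c = cost(a, it->first, it->second);
      if (c < bc) { bc = c; best = it->first; }
    }
    best_id[a] = best; best_c[a] = bc; dirty[a] = 0;
    *best_cost = bc;
    return best;
  }

  void merge(int a, int b) {
    int keep = a < b ? a : b, drop = a < b ? b : a;
    int shared = nb[keep][drop];
    n[keep] += n[drop];
    l[keep] += l[drop] - 2 * shared;
    for (int k = 0; k < B; ++k) {
      sum[(size_t)keep * B + k] += sum[(size_t)drop * B + k];
      sumsq[(size_t)keep * B + k] += sumsq[(size_t)drop * B + k];
    }
    minr[keep] = std::min(minr[keep], minr[drop]);
    maxr[keep] = std::max(maxr[keep], maxr[drop]);
    minc[keep] = std::min(minc[keep], minc[drop]);
    maxc[keep] = std::max(maxc[keep], maxc[drop]);
    nb[keep].erase(drop);
    for (std::map<int, int>::iterator it = nb[drop].begin();
         it != nb[drop].end(); ++it) {
      int k = it->first;
      if (k == keep) continue;
      nb[keep][k] += it->second;
      nb[k].erase(drop);
      nb[k][keep] += it->second;
    }
    nb[drop].clear();
    alive[drop] = 0;
    parent[drop] = keep;
    dirty[keep] = 1;
    for (std::map<int, int>::iterator it = nb[keep].begin();
         it != nb[keep].end(); ++it)
      dirty[it->first] = 1;
  }
};

} // namespace

// values: npix x B (column-major pixel order), NA rows = nodata.
// Returns 0-based surviving segment id per pixel (-1 for nodata) plus the
// final running statistics of each surviving segment for auditing.
// [[Rcpp::export]]
List fnea_merge_cpp(NumericMatrix values, int nrow, int ncol,
                    double scale, double shape_w, double cmpct_w,
                    NumericVector band_w, int connectivity) {
  const int npix = nrow * ncol, B = values.ncol();
  Graph g;
  g.npix = npix; g.B = B;
  g.shape_w = shape_w; g.cmpct_w = cmpct_w; g.scale2 = scale * scale;
  g.band_w.assign(band_w.begin(), band_w.end());
  g.alive.assign(npix, 0);
  g.n.assign(npix, 0); g.l.assign(npix, 0);
  g.minr.assign(npix, 0); g.maxr.assign(npix, 0);
  g.minc.assign(npix, 0); g.maxc.assign(npix, 0);
  g.parent.resize(npix);
  g.sum.assign((size_t)npix * B, 0.0);
  g.sumsq.assign((size_t)npix * B, 0.0);
  g.nb.resize(npix);
  g.dirty.assign(npix, 1);
  g.best_id.assign(npix, -1);
  g.best_c.assign(npix, R_PosInf);

  std::vector<char> valid(npix, 1);
  for (int p = 0; p < npix; ++p) {
    for (int k = 0; k < B; ++k)
      if (NumericVector::is_na(values(p, k))) { valid[p] = 0; break; }
  }

  for (int p = 0; p < npix; ++p) {
    g.parent[p] = p;
    if (!valid[p]) continue;
    g.alive[p] = 1;
    g.n[p] = 1; g.l[p] = 4;                 // 1-pixel perimeter is 4 edges
    int r = p % nrow, c = p / nrow;
    g.minr[p] = g.maxr[p] = r;
    g.minc[p] = g.maxc[p] = c;
    for (int k = 0; k < B; ++k) {
      double v = values(p, k);
      g.sum[(size_t)p * B + k] = v;
      g.sumsq[(size_t)p * B + k] = v * v;
    }
    // 4-neighbors share one pixel edge; diagonals (8-connectivity) share none
    if (r + 1 < nrow && valid[p + 1]) { g.nb[p][p + 1] = 1; g.nb[p + 1][p] = 1; }
    if (c + 1 < ncol && valid[p + nrow]) {
      g.nb[p][p + nrow] = 1; g.nb[p + nrow][p] = 1;
    }
    if (connectivity == 8) {
      if (r + 1 < nrow && c + 1 < ncol && valid[p + nrow + 1]) {
        g.nb[p][p + nrow + 1] = 0; g.nb[p + nrow + 1][p] = 0;
      }
      if (r > 0 && c + 1 < ncol && valid[p + nrow - 1]) {
        g.nb[p][p + nrow - 1] = 0; g.nb[p + nrow - 1][p] = 0;
      }
    }
  }

  bool merged = true;
  long n_merges = 0;
  while (merged) {
    merged = false;
    for (int i = 0; i < npix; ++i) {
      if (!g.alive[i] || g.nb[i].empty()) continue;
      double ci, cj;
      int j = g.best_neighbor(i, &ci);
      if (j < 0 || !(ci < g.scale2)) continue;
      int back = g.best_neighbor(j, &cj);
      if (back != i) continue;               // not mutual best
      g.merge(i, j);
      ++n_merges;
      merged = true;
    }
    Rcpp::checkUserInterrupt();
  }

  IntegerVector lab(npix);
  for (int p = 0; p < npix; ++p)
    lab[p] = valid[p] ? g.find(p) : -1;

  // surviving segment audit stats
  std::vector<int> surv;
  for (int p = 0; p < npix; ++p) if (g.alive[p]) surv.push_back(p);
  int K = (int)surv.size();
  IntegerVector seg_id(K), seg_n(K), seg_l(K);
  NumericMatrix seg_sum(K, B), seg_sumsq(K, B);
  for (int s = 0; s < K; ++s) {
    int p = surv[s];
    seg_id[s] = p; seg_n[s] = g.n[p]; seg_l[s] = g.l[p];
    for (int k = 0; k < B; ++k) {
      seg_sum(s, k) = g.sum[(size_t)p * B + k];
      seg_sumsq(s, k) = g.sumsq[(size_t)p * B + k];
    }
  }
  return List::create(_["labels0"] = lab, _["n_merges"] = (double)n_merges,
                      _["seg_id"] = seg_id, _["seg_n"] = seg_n,
                      _["seg_l"] = seg_l, _["seg_sum"] = seg_sum,
                      _["seg_sumsq"] = seg_sumsq);
}
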